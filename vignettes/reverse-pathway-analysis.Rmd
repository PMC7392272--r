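---
title: "Reverse pathway analysis of postnatal myocardial regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse pathway analysis of postnatal myocardial regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenpath)
```

## The scientific question

Neonatal pig hearts can regenerate myocardium lost to a myocardial
infarction (MI) induced on postnatal day 1 (P1), a capacity driven by
proliferation of pre-existing cardiomyocytes and lost within the first days
of life. regenpath implements the *reverse* strategy for asking which
signaling machinery drives this response: instead of screening expression
data against a pathway database and reading off a ranked list, a fixed
panel of candidate cell-cycle/cell-fate signaling pathways is chosen a
priori, each panel member is encoded as an explicit directed graph from its
initiating master regulators (ligands and receptors such as CSF1/CSF1R,
TGFB, NPPA) to its terminal effectors (transcription factors and
proliferative genes such as FOS, CCND1/2/3, PIM1), and a pathway is
declared **comprehensively upregulated** only when at least one complete
initiator-to-effector chain consists entirely of upregulated genes.

The pipeline starts from a raw gene-by-sample count matrix with a
five-group design — controls at P1, P7, P28 and MI tissue collected at P7
and P28, three biological replicates each — and proceeds in four stages:
normalization, gene-level classification, an exact concordance test, and
graph traversal.

## Normalization and group summaries

Counts are normalized with the median-of-ratios algorithm: for each gene
with positive counts in every sample, the ratio of its count to its
geometric mean across samples is formed, and a sample's size factor is the
median of those ratios. Factors are rescaled to geometric mean 1, which
pins down the otherwise arbitrary overall scale. The negative-binomial
generalized linear model that usually sits on top of this normalization is
deliberately out of scope — the downstream criteria work on group means and
their standard errors, not on shrunken dispersion estimates.

For every gene and group we report the arithmetic mean of normalized
counts, the standard error of that mean (SEM, the error-bar half-width used
throughout), the replicate count and the summed raw counts. A
single-replicate group gets SEM 0 by convention; the strict error-bar
criterion then degenerates to a strict mean inequality, which is reported
rather than an error so that incomplete designs still classify.

## Gene classification criteria

With pseudocount $c = 0.5$ (configurable) and fold threshold $\theta = 2$:

* **abundance**: raw counts summed over *all* samples must reach 200
  (inclusive — a total of exactly 200 passes);
* **early upregulation (P7)**: $(\bar x_{\mathrm{MI,P7}} + c) \ge
  \theta\,(\bar x_{\mathrm{CTL,P7}} + c)$, the SEM intervals must be
  strictly separated ($\bar x_{\mathrm{MI}} - s_{\mathrm{MI}} >
  \bar x_{\mathrm{CTL}} + s_{\mathrm{CTL}}$), and control expression must
  not increase from P1 to P7 ($\bar x_{\mathrm{CTL,P7}} \le
  \bar x_{\mathrm{CTL,P1}}$, zero tolerance, with a relaxation knob);
* **late upregulation (P28)**: the fold criterion alone;
* **late downregulation**: the mirrored fold criterion
  ($\mathrm{CTL} \ge \theta \times \mathrm{MI}$ at P28);
* **persistent**: early and late.

Two readings of the criteria coexist in the source material: the Methods
phrasing nests the late call inside the early one, while the figures mark
late-only genes. The default classifies early and late independently
(which reproduces the figures); `late_requires_early = TRUE` selects the
literal nested reading. Similarly `strict_late_separation` adds the
error-bar rule at P28 for users who want symmetric stringency. The
pseudocount (default 0.5) exists so genes silent in controls get a finite
fold; with pseudocount 0 and positive means the fold is the exact ratio of
means.

Note one deliberate asymmetry: every expression comparison uses normalized
values, but the abundance filter uses *raw* counts by definition, so it is
the one criterion not invariant to rescaling a library.

## The exact concordance p-value

For two groups of replicates that are fully separated (every MI value
strictly above every control value, i.e. $\min \mathrm{MI} > \max
\mathrm{CTL}$), the package reports two exact probabilities:

* `p_paper` $= 0.5^{n_A n_B}$, which treats the $n_A n_B$ pairwise
  orderings as independent fair coins; for 3 vs 3 this is $0.5^9 =
  0.001953125$, printed as 0.002 at three decimals;
* `p_rank` $= 1/\binom{n_A+n_B}{n_A}$, the probability under
  exchangeability that the pooled ranks split this extremely, computed by
  exhaustive enumeration of all rank assignments; for 3 vs 3 this is
  $1/20 = 0.05$.

The pairwise events are not independent — once the largest control value is
below the smallest MI value, many other comparisons are implied — so
`p_paper` systematically understates the exchangeability probability
(0.002 vs 0.05 at 3 vs 3). The all-pairwise form is kept as the primary
reported statistic for fidelity to the originating analysis; `p_rank` is
always reported alongside as the statistically defensible alternative, and
an exact-enumeration oracle plus a cross-check against the exact Wilcoxon
rank-sum tail guard its implementation. Any tie across groups makes the
configuration `mixed`: strict separation fails, `p_paper` is undefined
(reported as NA, never an error), and `p_rank` is still computed from
midranks. No attempt is made to reconstruct a general-case p-value for
non-separated configurations beyond the rank enumeration: the source
material's pointer for that case is uninterpretable, and guessing a method
would be worse than reporting the exact one we can defend.

```{r concordance}
concordance(c(5, 6, 7), c(1, 2, 3))
```

## Pathway graphs and the comprehensive call

Pathway topologies are packaged as JSON fixtures transcribed from the
study's flow charts, not re-derived from KEGG — the figures are the
authority for which nodes and edges were actually analyzed, and full KEGG
graphs differ. Nodes carry a role (initiator, intermediate, effector) and a
non-empty member list with OR semantics: "MAPK1/3" is satisfied if either
MAPK1 or MAPK3 is upregulated. Slash-named families are expanded through a
checked-in table (`family_members.tsv`) which also records symbol variants
in the source text (e.g. the gamma PKC isoform is PRKCG; "NKF1B" is taken
as NFKB1).

The headline call uses satisfaction mode `"any"` (upregulated at P7 and/or
P28). The caller restricts the graph to satisfied nodes and searches simple
paths from satisfied initiators to satisfied effectors; a pathway is
comprehensive iff at least one complete chain exists. This
one-complete-chain reading is interpretive but forced by the calls the
study itself makes: Hippo is called comprehensively upregulated even though
its core kinase cassette ends at the unchanged YAP1/WWTR1 node — the
TGFB–SMAD branch carries the call. Down-regulated nodes (CREB in the cAMP
pathway) never satisfy a chain and never break one; they are annotated
only. Cycles are permitted in the graphs; termination is guaranteed by the
simple-path restriction, and reported chains are capped (default 100) in
lexicographic node-id order for reproducibility. Persistence flags record
whether every initiator (resp. effector) on a satisfied chain is also
upregulated late.

Catalog entries without a detailed graph are reported as *not called*,
never as "not upregulated" — absence of a topology is not evidence.

```{r pathways}
statuses <- reported_gene_calls()
screen <- call_catalog(load_catalog(regenpath_fixture("catalog.json")), statuses)
screen
subset(screen$table, called)
```

## What the synthetic generator emulates

`generate_dataset()` reproduces the statistical structure the analysis
assumes so every stage is testable without sequencing data: five groups
with 3 replicates, per-gene baselines drawn log-normal (meanlog
$\log 400$, sdlog 1 — a realistic bulk RNA-seq abundance spread),
negative-binomial counts with size 10 (moderate biological overdispersion),
and per-sample library-size multipliers drawn log-uniformly in $[0.5, 2]$
so that normalization is genuinely exercised. Planted early genes use fold
4 at MI-P7 (persisting genes keep it at P28) and a two-fold control decline
from P1 to P7, emulating the postnatal down-regulation that the control
non-increase rule is designed to require. Four decoy kinds each violate
exactly one criterion in expectation: baseline mean 3 (raw totals ≈ 108,
under the 200 filter), inflated dispersion (size 0.5) at true fold 2 so SEM
bars overlap, a control drift (controls double from P1 to P7), and a
subthreshold fold of 1.5.

Truth semantics differ by mode, deliberately. In stochastic mode the truth
table records *intended* statuses (decoys are negatives), and validation is
aggregate — sensitivity and specificity over many seeds — because sampling
noise makes any single decoy's observed status probabilistic. In noise-free
mode (the infinite-dispersion limit, emitting exact rounded means) the
truth is derived by applying the classification arithmetic to the exact
planted means, so recovery is exact by construction; note that an
overlapping-bars decoy is then a legitimate positive, since its SEMs
collapse to zero. Pathway-level scenarios plant one member gene of every
node on the lexicographically first initiator-to-effector chain (or all but
a named break node), and the expected comprehensive flag is computed by an
independent generator-side depth-first search over the fixture topology.

What passing these tests does *not* show: the generator has no batch
effects beyond library size, no correlated genes, no length or GC biases,
and its decoys are stylized single-violation constructions. Recovery rates
on it bound the classifier's arithmetic correctness, not its performance on
real tissue.

## Numerical choices and problem sizes

* Size factors need at least one gene positive in every sample; otherwise
  normalization errors with advice, except in `classify_all()`, which falls
  back to unit factors (with a warning) so degenerate all-zero matrices
  classify as all-FALSE rather than crash.
* Fold comparisons are inclusive at the threshold ("at least two-fold");
  error-bar comparisons are strict, so touching bars fail.
* Rescaling one sample spreads a global factor $c^{1/n}$ across normalized
  values (a consequence of the geometric-mean-1 convention); status flags
  are exactly invariant, pseudocount-adjusted folds move only in the fourth
  decimal.
* Rank enumeration is exact and bounded (≤ 16 pooled values; the design
  here pools 6).
* The validation suite runs at deliberately small scale — hundreds to a
  thousand genes, 20 simulation seeds — chosen so the full suite completes
  in seconds while keeping the Monte-Carlo estimates stable to well under
  one percentage point.

## Known limitations

The pipeline starts at the count matrix: read QC, alignment and counting
are out of scope, as is the full negative-binomial testing framework. The
five packaged graphs encode the chains enumerated in the study's prose and
figures; branches the text leaves implicit (e.g. exact STAT family
membership) are encoded minimally and recorded in the fixture notes. The
all-pairwise p-value is reported for fidelity despite its independence
assumption being wrong; use `p_rank` for inference.
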