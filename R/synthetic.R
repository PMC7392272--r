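DECOY_KINDS <- c("low_abundance", "overlapping_bars", "control_drift",
                 "subthreshold_fold")

#' Configuration for the synthetic count generator
#'
#' Emulates the study design: five condition-by-timepoint groups (CTL-P1,
#' CTL-P7, CTL-P28, MI-P7, MI-P28) with 3 biological replicates each,
#' negative-binomial counts with a log-normal baseline across genes, and
#' planted MI effects with known truth. Planted-positive genes carry a
#' two-fold control decline from P1 to P7 (postnatal down-regulation), so
#' the control non-increase rule has a real margin; MI-P7 means are
#' baseline times the planted fold, and MI-P28 stays at the planted fold
#' for persisting genes. Four decoy kinds each violate exactly one
#' criterion in expectation: `low_abundance` (baseline mean 3, raw totals
#' well under 200), `overlapping_bars` (true fold 2 but dispersion inflated
#' so SEM bars overlap), `control_drift` (control expression doubles from
#' P1 to P7), `subthreshold_fold` (true fold 1.5).
#'
#' @param n_genes total gene count (planted genes included).
#' @param n_replicates replicates per group (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal location/scale of the
#'   per-gene baseline mean (defaults log(400) and 1).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param planted_early data.frame `gene_id`, `fold` (>= 1), `persists`
#'   (logical); NULL for none.
#' @param planted_decoys data.frame `gene_id`, `kind` (one of
#'   low_abundance, overlapping_bars, control_drift, subthreshold_fold);
#'   NULL for none.
#' @param libsize_range range of per-sample library-size multipliers,
#'   drawn log-uniformly (default c(0.5, 2)); c(1, 1) disables them.
#' @param noise_free emit exact group means rounded to integers instead of
#'   sampling (the infinite-dispersion limit); also disables library-size
#'   multipliers so recovery is exact.
#' @param seed integer seed; the single source of randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates = 3L,
                       baseline_meanlog = log(400),
                       baseline_sdlog = 1,
                       dispersion = 10,
                       planted_early = NULL,
                       planted_decoys = NULL,
                       libsize_range = c(0.5, 2),
                       noise_free = FALSE,
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_replicates < 1) stop("n_replicates must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2])
    stop("libsize_range must be an increasing pair of positive numbers")
  if (!is.null(planted_early)) {
    planted_early <- as.data.frame(planted_early, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "fold", "persists") %in% names(planted_early)))
    if (any(planted_early$fold < 1)) stop("planted folds must be >= 1")
  }
  if (!is.null(planted_decoys)) {
    planted_decoys <- as.data.frame(planted_decoys, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "kind") %in% names(planted_decoys)))
    bad <- setdiff(planted_decoys$kind, DECOY_KINDS)
    if (length(bad) > 0) stop("unknown decoy kind: ", bad[1])
  }
  ids <- c(if (!is.null(planted_early)) planted_early$gene_id,
           if (!is.null(planted_decoys)) planted_decoys$gene_id)
  if (anyDuplicated(ids)) stop("planted gene IDs must be distinct: ",
                               ids[duplicated(ids)][1])
  if (length(ids) > n_genes)
    stop("planted gene count (", length(ids), ") exceeds n_genes (", n_genes, ")")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 planted_early = planted_early,
                 planted_decoys = planted_decoys,
                 pathway_scenarios = list(),
                 libsize_range = libsize_range,
                 noise_free = noise_free,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# fixed decoy construction constants (part of the simulated study design)
LOW_ABUNDANCE_MEAN <- 3
OVERLAP_DISPERSION <- 0.5
SUBTHRESHOLD_FOLD <- 1.5
DRIFT_FACTOR <- 2
CONTROL_DECLINE <- 2
SCENARIO_FOLD <- 4

#' Plant a pathway-level scenario into a simulation config
#'
#' For `satisfied = TRUE`, every node on the lexicographically first
#' initiator-to-effector chain of the fixture gets its first member gene
#' planted as an early-upregulated gene (fold 4, persisting). For
#' `satisfied = FALSE`, a `break_node` on such a chain must be named: all
#' chain nodes except the break node are planted, and whether the pathway
#' still has a complete satisfied chain is decided from the fixture
#' topology at generation time (shared genes planted by other scenarios
#' are taken into account).
#'
#' @param cfg a [sim_config()].
#' @param fixture a `pathway_graph` from [load_pathway()].
#' @param satisfied plant a complete chain (TRUE) or a broken one (FALSE).
#' @param break_node node_id left unplanted when `satisfied = FALSE`.
#' @param fold planted fold (default 4).
#' @param persists planted genes stay upregulated at P28 (default TRUE).
#' @return The augmented `sim_config`.
#' @export
plant_pathway_scenario <- function(cfg, fixture, satisfied = TRUE,
                                   break_node = NULL, fold = SCENARIO_FOLD,
                                   persists = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(fixture, "pathway_graph"))
  chains <- enumerate_chains(fixture)
  if (length(chains) == 0)
    stop("fixture '", fixture$pathway_id,
         "' has no initiator-to-effector chain to plant")
  if (!satisfied) {
    if (is.null(break_node))
      stop("a break_node is required for an unsatisfied scenario")
    if (!break_node %in% fixture$nodes$node_id)
      stop("break_node '", break_node, "' is not a node of pathway '",
           fixture$pathway_id, "'")
    chains <- Filter(function(ch) break_node %in% ch, chains)
    if (length(chains) == 0)
      stop("break_node '", break_node, "' lies on no initiator-to-effector chain")
  }
  chain <- chains[[1]]
  plant_nodes <- if (satisfied) chain else setdiff(chain, break_node)
  members <- vapply(plant_nodes, function(nid) {
    fixture$nodes$members[[match(nid, fixture$nodes$node_id)]][1]
  }, character(1))
  already <- if (is.null(cfg$planted_early)) character(0) else cfg$planted_early$gene_id
  new <- setdiff(members, already)
  if (length(new) > 0) {
    add <- data.frame(gene_id = new, fold = fold, persists = persists,
                      stringsAsFactors = FALSE)
    cfg$planted_early <- rbind(cfg$planted_early, add)
  }
  n_planted <- nrow(cfg$planted_early) +
    if (is.null(cfg$planted_decoys)) 0 else nrow(cfg$planted_decoys)
  if (n_planted > cfg$n_genes)
    stop("planted gene count exceeds n_genes after scenario planting")
  cfg$pathway_scenarios <- c(cfg$pathway_scenarios,
                             list(list(pathway_id = fixture$pathway_id,
                                       graph = fixture,
                                       satisfied = satisfied,
                                       break_node = break_node)))
  cfg
}

# all simple initiator->effector node-id paths, lexicographically sorted
enumerate_chains <- function(g) {
  ig <- pathway_igraph(g)
  inits <- sort(g$nodes$node_id[g$nodes$role == "initiator"])
  effs <- sort(g$nodes$node_id[g$nodes$role == "effector"])
  chains <- list()
  for (f in inits) {
    ps <- igraph::all_simple_paths(ig, from = f, to = effs, mode = "out")
    chains <- c(chains, lapply(ps, igraph::as_ids))
    if (f %in% effs) chains <- c(chains, list(f))
  }
  if (length(chains) == 0) return(chains)
  chains[order(vapply(chains, paste, "", collapse = "\r"))]
}

# generator-side reachability check, independent of the pathway caller:
# plain recursive DFS over edge lists restricted to satisfied nodes
scenario_expected_comprehensive <- function(g, early_genes) {
  sat <- vapply(seq_len(nrow(g$nodes)),
                function(i) any(g$nodes$members[[i]] %in% early_genes),
                logical(1))
  names(sat) <- g$nodes$node_id
  effs <- g$nodes$node_id[g$nodes$role == "effector" & sat]
  inits <- g$nodes$node_id[g$nodes$role == "initiator" & sat]
  if (length(effs) == 0 || length(inits) == 0) return(FALSE)
  adj <- split(g$edges[, "to"], factor(g$edges[, "from"],
                                       levels = g$nodes$node_id))
  visit <- function(node, seen) {
    if (node %in% effs) return(TRUE)
    for (nxt in adj[[node]]) {
      if (!sat[nxt] || nxt %in% seen) next
      if (visit(nxt, c(seen, nxt))) return(TRUE)
    }
    FALSE
  }
  any(vapply(inits, function(f) visit(f, f), logical(1)))
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws negative-binomial counts (or exact rounded means in noise-free
#' mode) according to the configuration and returns the matrix together
#' with a truth table. In stochastic mode the truth records *intended*
#' statuses — planted genes TRUE, decoys and background FALSE — and
#' validation against it is aggregate (sensitivity/specificity), since
#' sampling noise makes any single gene's observed status probabilistic.
#' In noise-free mode the truth is derived by applying the classification
#' arithmetic to the exact planted group means, so recovery is exact by
#' construction.
#'
#' @param cfg a [sim_config()], possibly augmented by
#'   [plant_pathway_scenario()].
#' @param truth_config the [classifier_config()] the noise-free truth is
#'   evaluated under (default settings reproduce the study criteria).
#' @return List: `matrix` (a [count_matrix()]), `truth` (list with
#'   `genes` — data.frame `gene_id`, `expected_passes_abundance`,
#'   `expected_early_up`, `expected_late_up` — and `pathways` — data.frame
#'   `pathway_id`, `expected_comprehensive`).
#' @export
generate_dataset <- function(cfg, truth_config = classifier_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nrep <- cfg$n_replicates
  groups <- c("CTL.P1", "CTL.P7", "CTL.P28", "MI.P7", "MI.P28")

  planted <- if (is.null(cfg$planted_early))
    data.frame(gene_id = character(0), fold = numeric(0), persists = logical(0))
  else cfg$planted_early
  decoys <- if (is.null(cfg$planted_decoys))
    data.frame(gene_id = character(0), kind = character(0))
  else cfg$planted_decoys

  special <- c(planted$gene_id, decoys$gene_id)
  n_filler <- cfg$n_genes - length(special)
  filler <- sprintf("gene_%05d", seq_len(n_filler))
  genes <- c(special, filler)

  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- genes
  size <- rep(cfg$dispersion, cfg$n_genes)
  names(size) <- genes

  # per-gene expected means for the five groups
  mu <- matrix(rep(baseline, times = 5), ncol = 5,
               dimnames = list(genes, groups))
  mu[, "CTL.P1"] <- baseline   # background genes: flat everywhere

  if (nrow(planted) > 0) {
    i <- planted$gene_id
    mu[i, "CTL.P1"] <- CONTROL_DECLINE * baseline[i]
    mu[i, "MI.P7"] <- planted$fold * baseline[i]
    mu[i, "MI.P28"] <- ifelse(planted$persists,
                              planted$fold * baseline[i], baseline[i])
  }
  for (j in seq_len(nrow(decoys))) {
    gid <- decoys$gene_id[j]
    b <- baseline[gid]
    switch(decoys$kind[j],
           low_abundance = {
             b <- LOW_ABUNDANCE_MEAN
             baseline[gid] <- b
             mu[gid, ] <- c(CONTROL_DECLINE * b, b, b, 4 * b, 4 * b)
           },
           overlapping_bars = {
             mu[gid, ] <- c(CONTROL_DECLINE * b, b, b, 2 * b, b)
             size[gid] <- OVERLAP_DISPERSION
           },
           control_drift = {
             mu[gid, ] <- c(b, DRIFT_FACTOR * b, DRIFT_FACTOR * b,
                            2 * DRIFT_FACTOR * b, DRIFT_FACTOR * b)
           },
           subthreshold_fold = {
             mu[gid, ] <- c(CONTROL_DECLINE * b, b, b, SUBTHRESHOLD_FOLD * b, b)
           })
  }

  sample_ids <- as.vector(vapply(groups, function(g)
    paste(sub(".", "_", g, fixed = TRUE), seq_len(nrep), sep = "_"),
    character(nrep)))
  design <- data.frame(
    sample_id = sample_ids,
    condition = rep(sub("\\..*$", "", groups), each = nrep),
    timepoint = rep(sub("^.*\\.", "", groups), each = nrep),
    replicate = rep(seq_len(nrep), times = 5),
    stringsAsFactors = FALSE)

  libmult <- if (cfg$noise_free || identical(cfg$libsize_range, c(1, 1)))
    rep(1, length(sample_ids))
  else exp(stats::runif(length(sample_ids), log(cfg$libsize_range[1]),
                        log(cfg$libsize_range[2])))

  counts <- matrix(0L, nrow = cfg$n_genes, ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (s in seq_along(sample_ids)) {
    gmu <- mu[, groups[ceiling(s / nrep)]] * libmult[s]
    counts[, s] <- if (cfg$noise_free) as.integer(round(gmu))
    else stats::rnbinom(cfg$n_genes, mu = gmu, size = size)
  }
  m <- count_matrix(counts, design)

  truth_genes <- if (cfg$noise_free)
    noise_free_truth(m, mu, nrep, truth_config)
  else intended_truth(genes, planted, decoys, mu, nrep, truth_config)

  early_set <- truth_genes$gene_id[truth_genes$expected_early_up]
  truth_paths <- data.frame(pathway_id = character(0),
                            expected_comprehensive = logical(0))
  if (length(cfg$pathway_scenarios) > 0) {
    truth_paths <- do.call(rbind, lapply(cfg$pathway_scenarios, function(sc) {
      data.frame(pathway_id = sc$pathway_id,
                 expected_comprehensive =
                   if (sc$satisfied) TRUE
                 else scenario_expected_comprehensive(sc$graph, early_set),
                 stringsAsFactors = FALSE)
    }))
  }
  list(matrix = m, truth = list(genes = truth_genes, pathways = truth_paths))
}

# noise-free: flags follow from the exact emitted means (SEMs are all 0)
noise_free_truth <- function(m, mu, nrep, cfg) {
  r <- round(mu)
  raw_total <- as.integer(nrep * rowSums(r))
  pc <- cfg$pseudocount
  thr <- cfg$fold_threshold
  abund <- raw_total >= cfg$min_raw_total
  fold7 <- (r[, "MI.P7"] + pc) / (r[, "CTL.P7"] + pc)
  fold28 <- (r[, "MI.P28"] + pc) / (r[, "CTL.P28"] + pc)
  early <- abund & fold7 >= thr &
    (r[, "MI.P7"] > r[, "CTL.P7"]) &          # strict separation, zero SEMs
    (r[, "CTL.P7"] <= r[, "CTL.P1"])
  late <- abund & fold28 >= thr
  if (cfg$late_requires_early) late <- late & early
  data.frame(gene_id = rownames(mu),
             expected_passes_abundance = unname(abund),
             expected_early_up = unname(early),
             expected_late_up = unname(late),
             stringsAsFactors = FALSE, row.names = NULL)
}

# stochastic: intended statuses (decoys negative by design)
intended_truth <- function(genes, planted, decoys, mu, nrep, cfg) {
  abund <- (nrep * rowSums(mu)) >= cfg$min_raw_total
  early <- stats::setNames(rep(FALSE, length(genes)), genes)
  late <- early
  if (nrow(planted) > 0) {
    pos <- planted$fold >= cfg$fold_threshold
    early[planted$gene_id[pos]] <- TRUE
    late[planted$gene_id[pos & planted$persists]] <- TRUE
  }
  data.frame(gene_id = genes,
             expected_passes_abundance = unname(abund[genes]),
             expected_early_up = unname(early),
             expected_late_up = unname(late),
             stringsAsFactors = FALSE, row.names = NULL)
}
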