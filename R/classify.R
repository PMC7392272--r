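#' Configuration for the gene upregulation classifier
#'
#' Defaults reproduce the study criteria exactly: at-least-two-fold MI/CTL
#' mean ratio (boundary inclusive), a minimum of 200 raw counts summed over
#' all samples (inclusive), strict error-bar separation at P7
#' (MI lower bound strictly above the CTL upper bound), and no increase in
#' control expression from P1 to P7.
#'
#' @param fold_threshold minimum MI/CTL mean ratio, >= 1 (default 2).
#' @param min_raw_total minimum raw-count sum over all samples (default 200).
#' @param require_error_bar_separation_p7 require strict SEM-bar separation
#'   at P7 for an early call (default TRUE).
#' @param require_control_nonincrease require mean CTL-P7 <= mean CTL-P1
#'   for an early call (default TRUE).
#' @param pseudocount added to both means in every fold-ratio comparison
#'   (default 0.5).
#' @param control_tolerance slack allowed in the control non-increase rule:
#'   the rule becomes mean CTL-P7 <= (1 + tol) * mean CTL-P1 (default 0).
#' @param late_requires_early restrict late upregulation to genes already
#'   called early (the literal nested reading of the criteria). Default
#'   FALSE: early and late are classified independently, which is what the
#'   pathway-figure annotations (late-only genes in red text without a red
#'   box) require.
#' @param strict_late_separation also require SEM-bar separation at P28 for
#'   a late call (default FALSE; the stated late criterion is fold-only).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(fold_threshold = 2,
                              min_raw_total = 200L,
                              require_error_bar_separation_p7 = TRUE,
                              require_control_nonincrease = TRUE,
                              pseudocount = 0.5,
                              control_tolerance = 0,
                              late_requires_early = FALSE,
                              strict_late_separation = FALSE) {
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  if (min_raw_total < 0) stop("min_raw_total must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (control_tolerance < 0) stop("control_tolerance must be >= 0")
  structure(list(fold_threshold = fold_threshold,
                 min_raw_total = as.integer(min_raw_total),
                 require_error_bar_separation_p7 = require_error_bar_separation_p7,
                 require_control_nonincrease = require_control_nonincrease,
                 pseudocount = pseudocount,
                 control_tolerance = control_tolerance,
                 late_requires_early = late_requires_early,
                 strict_late_separation = strict_late_separation),
            class = "classifier_config")
}

#' Raw-count abundance filter
#'
#' TRUE iff the gene's raw counts summed over every sample reach the
#' configured minimum (inclusive at the boundary: a total of exactly 200
#' passes the default filter).
#'
#' @param m a [count_matrix()].
#' @param gene gene ID (must be present).
#' @param cfg a [classifier_config()].
#' @return Logical scalar.
#' @export
passes_abundance <- function(m, gene, cfg = classifier_config()) {
  stopifnot(inherits(m, "count_matrix"))
  if (!gene %in% rownames(m$counts)) stop("unknown gene: ", gene)
  sum(m$counts[gene, ]) >= cfg$min_raw_total
}

#' Apply the upregulation criteria to one gene's group statistics
#'
#' The arithmetic core of the classifier, exposed so the decision rules can
#' be exercised on hand-built summaries. `stats` is a list with normalized
#' group means/SEMs (`mean_ctl_p1`, `mean_ctl_p7`, `sem_ctl_p7`,
#' `mean_mi_p7`, `sem_mi_p7`, `mean_ctl_p28`, `mean_mi_p28`, and optionally
#' `sem_ctl_p28`, `sem_mi_p28`) plus `raw_total`, the gene's raw-count sum
#' over all samples. Missing (NA or absent) groups disable the calls that
#' depend on them.
#'
#' Rules (pc = pseudocount, thr = fold threshold):
#' * early_up: abundance, (mean_mi_p7+pc) >= thr*(mean_ctl_p7+pc),
#'   strictly separated SEM bars at P7, and control non-increase
#'   mean_ctl_p7 <= mean_ctl_p1.
#' * late_up: abundance and (mean_mi_p28+pc) >= thr*(mean_ctl_p28+pc)
#'   (fold-only).
#' * late_down: abundance and (mean_ctl_p28+pc) >= thr*(mean_mi_p28+pc).
#' * persistent: early_up and late_up.
#'
#' @param stats list or one-row data.frame as described above.
#' @param cfg a [classifier_config()].
#' @return List with logicals `passes_abundance`, `early_up`, `late_up`,
#'   `late_down`, `persistent` and numerics `fold_p7`, `fold_p28`.
#' @export
apply_gene_criteria <- function(stats, cfg = classifier_config()) {
  g <- function(name) {
    v <- stats[[name]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }
  pc <- cfg$pseudocount
  thr <- cfg$fold_threshold
  abund <- !is.na(g("raw_total")) && g("raw_total") >= cfg$min_raw_total

  fold_p7 <- (g("mean_mi_p7") + pc) / (g("mean_ctl_p7") + pc)
  fold_p28 <- (g("mean_mi_p28") + pc) / (g("mean_ctl_p28") + pc)

  early <- abund && !is.na(fold_p7) && fold_p7 >= thr
  if (early && cfg$require_error_bar_separation_p7) {
    sep <- (g("mean_mi_p7") - g("sem_mi_p7")) > (g("mean_ctl_p7") + g("sem_ctl_p7"))
    early <- !is.na(sep) && sep
  }
  if (early && cfg$require_control_nonincrease) {
    ni <- g("mean_ctl_p7") <= (1 + cfg$control_tolerance) * g("mean_ctl_p1")
    early <- !is.na(ni) && ni
  }

  late <- abund && !is.na(fold_p28) && fold_p28 >= thr
  if (late && cfg$strict_late_separation) {
    sep28 <- (g("mean_mi_p28") - g("sem_mi_p28")) >
      (g("mean_ctl_p28") + g("sem_ctl_p28"))
    late <- !is.na(sep28) && sep28
  }
  if (cfg$late_requires_early) late <- late && early

  down <- abund && !is.na(fold_p28) && (1 / fold_p28) >= thr

  list(passes_abundance = abund, early_up = early, late_up = late,
       late_down = down, persistent = early && late,
       fold_p7 = fold_p7, fold_p28 = fold_p28)
}

# pull one gene's statistics out of a group-summary table
gene_stats_from_summaries <- function(sums, gene) {
  pick <- function(cond, tp, field) {
    r <- summary_row(sums, gene, cond, tp)
    if (is.null(r)) NA_real_ else r[[field]]
  }
  rows <- sums[sums$gene_id == gene, , drop = FALSE]
  list(mean_ctl_p1 = pick("CTL", "P1", "mean_norm"),
       mean_ctl_p7 = pick("CTL", "P7", "mean_norm"),
       sem_ctl_p7 = pick("CTL", "P7", "sem_norm"),
       mean_mi_p7 = pick("MI", "P7", "mean_norm"),
       sem_mi_p7 = pick("MI", "P7", "sem_norm"),
       mean_ctl_p28 = pick("CTL", "P28", "mean_norm"),
       sem_ctl_p28 = pick("CTL", "P28", "sem_norm"),
       mean_mi_p28 = pick("MI", "P28", "mean_norm"),
       sem_mi_p28 = pick("MI", "P28", "sem_norm"),
       raw_total = sum(rows$raw_total))
}

#' Classify one gene from group summaries
#'
#' @param sums group summaries from [summarize_groups()].
#' @param m the [count_matrix()] the summaries came from (raw counts feed
#'   the abundance filter).
#' @param gene gene ID.
#' @param cfg a [classifier_config()].
#' @return One-row data.frame with the status flags and fold changes.
#' @export
classify_gene <- function(sums, m, gene, cfg = classifier_config()) {
  stopifnot(inherits(m, "count_matrix"))
  if (!gene %in% rownames(m$counts)) stop("unknown gene: ", gene)
  st <- gene_stats_from_summaries(sums, gene)
  st$raw_total <- sum(m$counts[gene, ])
  res <- apply_gene_criteria(st, cfg)
  data.frame(gene_id = gene,
             passes_abundance = res$passes_abundance,
             early_up = res$early_up, late_up = res$late_up,
             late_down = res$late_down, persistent = res$persistent,
             log2fc_P7 = log2(res$fold_p7), log2fc_P28 = log2(res$fold_p28),
             stringsAsFactors = FALSE)
}

#' Classify every gene in a count matrix
#'
#' Runs normalization, group summarization, the upregulation criteria, and
#' the exact concordance test on the MI-P7 versus CTL-P7 normalized
#' replicate values of each gene. Deterministic: identical inputs give
#' identical output, genes reported in matrix order.
#'
#' @param m a [count_matrix()].
#' @param cfg a [classifier_config()].
#' @param with_concordance attach per-gene concordance p-values for the P7
#'   comparison (default TRUE; requires MI-P7 and CTL-P7 samples).
#' @return data.frame with one row per gene: status flags, log2 fold
#'   changes at P7/P28, and `p_concordance_P7` / `p_rank_P7` (NA when the
#'   configuration is mixed or groups are absent).
#' @export
classify_all <- function(m, cfg = classifier_config(), with_concordance = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  # degenerate matrices (no gene positive everywhere) fall back to unit
  # size factors so zero-expression genes classify as all-FALSE instead of
  # failing normalization
  sf <- tryCatch(size_factors(m), error = function(e) {
    warning("median-of-ratios undefined (no all-positive gene); ",
            "using unit size factors")
    stats::setNames(rep(1, ncol(m$counts)), colnames(m$counts))
  })
  norm <- normalize_counts(m, sf)
  sums <- summarize_groups(m, sf)
  genes <- rownames(m$counts)
  keys <- group_key(m$design)

  wide <- function(cond, tp, field) {
    idx <- sums$condition == cond & sums$timepoint == tp
    if (!any(idx)) return(stats::setNames(rep(NA_real_, length(genes)), genes))
    sub <- sums[idx, , drop = FALSE]
    stats::setNames(sub[[field]], sub$gene_id)[genes]
  }
  pc <- cfg$pseudocount
  thr <- cfg$fold_threshold
  raw_total <- rowSums(m$counts)
  abund <- raw_total >= cfg$min_raw_total

  m_ctl1 <- wide("CTL", "P1", "mean_norm")
  m_ctl7 <- wide("CTL", "P7", "mean_norm"); s_ctl7 <- wide("CTL", "P7", "sem_norm")
  m_mi7 <- wide("MI", "P7", "mean_norm");  s_mi7 <- wide("MI", "P7", "sem_norm")
  m_ctl28 <- wide("CTL", "P28", "mean_norm"); s_ctl28 <- wide("CTL", "P28", "sem_norm")
  m_mi28 <- wide("MI", "P28", "mean_norm");  s_mi28 <- wide("MI", "P28", "sem_norm")

  fold7 <- (m_mi7 + pc) / (m_ctl7 + pc)
  fold28 <- (m_mi28 + pc) / (m_ctl28 + pc)

  early <- abund & !is.na(fold7) & fold7 >= thr
  if (cfg$require_error_bar_separation_p7)
    early <- early & !is.na(s_mi7) & ((m_mi7 - s_mi7) > (m_ctl7 + s_ctl7))
  if (cfg$require_control_nonincrease)
    early <- early & !is.na(m_ctl1) &
      (m_ctl7 <= (1 + cfg$control_tolerance) * m_ctl1)
  early[is.na(early)] <- FALSE

  late <- abund & !is.na(fold28) & fold28 >= thr
  if (cfg$strict_late_separation)
    late <- late & !is.na(s_mi28) & ((m_mi28 - s_mi28) > (m_ctl28 + s_ctl28))
  late[is.na(late)] <- FALSE
  if (cfg$late_requires_early) late <- late & early

  down <- abund & !is.na(fold28) & (1 / fold28) >= thr
  down[is.na(down)] <- FALSE

  p_paper7 <- rep(NA_real_, length(genes))
  p_rank7 <- rep(NA_real_, length(genes))
  mi_cols <- which(keys == "MI.P7")
  ctl_cols <- which(keys == "CTL.P7")
  if (with_concordance && length(mi_cols) > 0 && length(ctl_cols) > 0) {
    for (i in seq_along(genes)) {
      cc <- concordance(norm[i, mi_cols], norm[i, ctl_cols])
      p_paper7[i] <- cc$p_paper
      p_rank7[i] <- cc$p_rank
    }
  }

  out <- data.frame(gene_id = genes,
                    passes_abundance = unname(abund),
                    early_up = unname(early), late_up = unname(late),
                    late_down = unname(down),
                    persistent = unname(early & late),
                    log2fc_P7 = unname(log2(fold7)),
                    log2fc_P28 = unname(log2(fold28)),
                    p_concordance_P7 = p_paper7, p_rank_P7 = p_rank7,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene statuses to a TSV file and return category counts
#'
#' @param statuses output of [classify_all()].
#' @param path output TSV path (NULL to skip writing).
#' @return Invisibly, a list of category counts
#'   (`n_genes`, `n_pass_abundance`, `n_early_up`, `n_late_up`,
#'   `n_late_down`, `n_persistent`).
#' @export
write_gene_status <- function(statuses, path = NULL) {
  if (!is.null(path))
    utils::write.table(statuses, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(n_genes = nrow(statuses),
                 n_pass_abundance = sum(statuses$passes_abundance),
                 n_early_up = sum(statuses$early_up),
                 n_late_up = sum(statuses$late_up),
                 n_late_down = sum(statuses$late_down),
                 n_persistent = sum(statuses$persistent)))
}
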