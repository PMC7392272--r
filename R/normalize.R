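#' Median-of-ratios size factors
#'
#' Computes one positive scaling constant per sample by the median-of-ratios
#' algorithm: for each gene with strictly positive counts in every sample
#' (the reference set), the ratio of its count in sample j to its geometric
#' mean across samples is formed; the size factor of sample j is the median
#' of those ratios. Factors are rescaled so their geometric mean is 1,
#' which removes the overall scale indeterminacy. Dividing a sample's raw
#' counts by its size factor yields normalized counts.
#'
#' @param m a [count_matrix()] or a non-negative integer matrix.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
size_factors <- function(m) {
  k <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  ref <- rowSums(k > 0) == ncol(k)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "add a pseudocount or include more genes before normalizing")
  logk <- log(k[ref, , drop = FALSE])
  loggeo <- rowMeans(logk)
  logratios <- logk - loggeo
  logsf <- apply(logratios, 2, stats::median)
  logsf <- logsf - mean(logsf)   # geometric mean 1
  stats::setNames(exp(logsf), colnames(k))
}

#' Divide raw counts by size factors
#'
#' @param m a [count_matrix()].
#' @param sf size factors as returned by [size_factors()]; computed if NULL.
#' @return Numeric matrix of normalized counts, same dimnames as the input.
#' @export
normalize_counts <- function(m, sf = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(sf)) sf <- size_factors(m)
  if (any(sf <= 0)) stop("size factors must be positive")
  sweep(m$counts, 2, sf[colnames(m$counts)], "/")
}

#' Per-gene per-group normalized summaries
#'
#' For every gene and every condition-by-timepoint group present in the
#' design, reports the arithmetic mean of normalized counts, the standard
#' error of that mean (sample standard deviation / sqrt(n); 0 when n = 1),
#' the replicate count, and the summed raw counts within the group. The SEM
#' is the error-bar half-width used by the upregulation criteria.
#'
#' @param m a [count_matrix()].
#' @param sf optional size factors; computed if NULL.
#' @return data.frame with columns `gene_id`, `condition`, `timepoint`,
#'   `n`, `raw_total`, `mean_norm`, `sem_norm`; one row per gene x group,
#'   genes in matrix order, groups in CTL.P1, CTL.P7, CTL.P28, MI.P7,
#'   MI.P28 order (present groups only).
#' @export
summarize_groups <- function(m, sf = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  norm <- normalize_counts(m, sf)
  keys <- group_key(m$design)
  order_all <- c("CTL.P1", "CTL.P7", "CTL.P28", "MI.P7", "MI.P28")
  groups <- intersect(order_all, unique(keys))
  out <- lapply(groups, function(g) {
    j <- which(keys == g)
    sub <- norm[, j, drop = FALSE]
    n <- length(j)
    mu <- rowMeans(sub)
    sem <- if (n > 1) apply(sub, 1, stats::sd) / sqrt(n) else rep(0, nrow(sub))
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(gene_id = rownames(m$counts),
               condition = parts[1], timepoint = parts[2],
               n = n,
               raw_total = as.integer(rowSums(m$counts[, j, drop = FALSE])),
               mean_norm = mu, sem_norm = sem,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$gene_id, rownames(m$counts)),
                   match(paste(res$condition, res$timepoint, sep = "."),
                         order_all)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# fetch the summary row for one gene x group, or NULL when absent
summary_row <- function(sums, gene, condition, timepoint) {
  i <- which(sums$gene_id == gene & sums$condition == condition &
               sums$timepoint == timepoint)
  if (length(i) == 0) return(NULL)
  sums[i[1], , drop = FALSE]
}

#' MI-versus-control fold change at one timepoint
#'
#' fold = (mean_MI + pseudocount) / (mean_CTL + pseudocount) on normalized
#' group means; log2fc = log2(fold). The pseudocount keeps the ratio
#' finite for genes silent in controls; with pseudocount 0 and positive
#' means the result is the exact ratio of means.
#'
#' @param sums group summaries from [summarize_groups()].
#' @param gene gene ID.
#' @param timepoint `"P7"` or `"P28"`.
#' @param pseudocount non-negative real added to both means (default 0.5).
#' @param p_concordance optional concordance p-value to attach.
#' @return data.frame row: `gene_id`, `timepoint`, `log2fc`, `fold`,
#'   `p_concordance` (NA when not supplied).
#' @export
fold_change <- function(sums, gene, timepoint, pseudocount = 0.5,
                        p_concordance = NA_real_) {
  if (!timepoint %in% c("P7", "P28"))
    stop("fold change is defined at P7 and P28 (MI collection timepoints)")
  mi <- summary_row(sums, gene, "MI", timepoint)
  ctl <- summary_row(sums, gene, "CTL", timepoint)
  if (is.null(mi) || is.null(ctl))
    stop(sprintf("gene '%s' lacks %s summaries at %s", gene,
                 if (is.null(mi)) "MI" else "CTL", timepoint))
  fold <- (mi$mean_norm + pseudocount) / (ctl$mean_norm + pseudocount)
  data.frame(gene_id = gene, timepoint = timepoint,
             log2fc = log2(fold), fold = fold,
             p_concordance = p_concordance,
             stringsAsFactors = FALSE)
}

#' Write group summaries to a TSV file
#' @param sums output of [summarize_groups()].
#' @param path output path.
#' @return Invisibly, `sums`.
#' @export
write_group_summaries <- function(sums, path) {
  utils::write.table(sums, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sums)
}
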