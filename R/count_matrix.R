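VALID_CONDITIONS <- c("CTL", "MI")
VALID_TIMEPOINTS <- c("P1", "P7", "P28")

#' Construct a validated count matrix with its sample design
#'
#' Bundles a raw gene-by-sample integer count matrix with the experimental
#' design (condition and postnatal timepoint per sample). MI is induced at
#' P1 and tissue collected at P7 and P28, so MI samples may only carry the
#' P7 or P28 timepoint; controls exist at P1, P7 and P28.
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs). All entries must be
#'   non-negative integers.
#' @param design data.frame with columns `sample_id`, `condition`
#'   (`"MI"` or `"CTL"`), `timepoint` (`"P1"`, `"P7"`, `"P28"`) and
#'   `replicate` (positive integer). One row per column of `counts`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `design` (data.frame, rows ordered to
#'   match the columns of `counts`).
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ID in counts: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ID in counts: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count for gene '%s' in sample '%s' is not a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "timepoint", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0)
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1])
  if (!all(design$condition %in% VALID_CONDITIONS))
    stop("condition must be one of: ", paste(VALID_CONDITIONS, collapse = ", "))
  if (!all(design$timepoint %in% VALID_TIMEPOINTS))
    stop("timepoint must be one of: ", paste(VALID_TIMEPOINTS, collapse = ", "))
  design$replicate <- as.integer(design$replicate)
  if (any(is.na(design$replicate)) || any(design$replicate < 1))
    stop("replicate must be a positive integer")
  if (any(design$condition == "MI" & design$timepoint == "P1"))
    stop("MI samples exist only at P7 and P28 (injury is induced at P1)")

  not_in_design <- setdiff(colnames(counts), design$sample_id)
  if (length(not_in_design) > 0)
    stop("sample '", not_in_design[1], "' in counts has no design row")
  not_in_counts <- setdiff(design$sample_id, colnames(counts))
  if (length(not_in_counts) > 0)
    stop("sample '", not_in_counts[1], "' in design has no counts column")
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL

  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' Read a count matrix and its design from TSV files
#'
#' The counts file is tab-separated with a header row of sample IDs and
#' gene IDs in the first column; the design file is tab-separated with
#' columns `sample_id`, `condition`, `timepoint`, `replicate`. Gene IDs
#' are case-preserved and not normalized.
#'
#' @param counts_path path to counts TSV.
#' @param design_path path to design TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(design_path)) stop("design file not found: ", design_path)
  tab <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tab) < 2) stop("counts file needs a gene-ID column and >=1 sample column")
  gene_ids <- tab[[1]]
  vals <- tab[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(vals) > 0 && length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    stop(sprintf(
      "count for gene '%s' in sample '%s' is '%s' (must be a non-negative integer)",
      gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]))
  }
  m <- matrix(as.integer(num), nrow = nrow(vals),
              dimnames = list(gene_ids, colnames(vals)))
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  count_matrix(m, design)
}

#' Write a count matrix and design to TSV files
#'
#' @param m a [count_matrix()].
#' @param counts_path,design_path output paths.
#' @return Invisibly, `m`.
#' @export
write_counts <- function(m, counts_path, design_path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' @export
print.count_matrix <- function(x, ...) {
  grp <- interaction(x$design$condition, x$design$timepoint, drop = TRUE)
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(grp), table(grp), sep = ":", collapse = ", ")))
  invisible(x)
}

# group key helper: "MI.P7" style labels, design order preserved
group_key <- function(design) paste(design$condition, design$timepoint, sep = ".")
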