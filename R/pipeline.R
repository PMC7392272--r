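#' Write a synthetic dataset to disk
#'
#' Runs [generate_dataset()] and writes the counts TSV, design TSV and
#' truth JSON under `out_dir` (`counts.tsv`, `design.tsv`, `truth.json`).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the list returned by [generate_dataset()].
#' @export
simulate_dataset <- function(cfg, out_dir) {
  res <- generate_dataset(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(res$matrix, file.path(out_dir, "counts.tsv"),
               file.path(out_dir, "design.tsv"))
  jsonlite::write_json(res$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Run the full reverse pathway analysis
#'
#' counts -> size factors -> group summaries -> gene statuses ->
#' pathway calls -> report. Exactly one of (`counts_path` + `design_path`)
#' or `sim` must be supplied. Output files are deterministic (gene and
#' pathway order fixed by the inputs): `group_summaries.tsv`,
#' `fold_changes.tsv`, `gene_status.tsv`, `pathway_calls.json`,
#' `pathway_summary.tsv` and `report.json`.
#'
#' @param counts_path,design_path input TSVs (see [read_counts()]).
#' @param sim a [sim_config()] to simulate input instead of reading files.
#' @param catalog_path pathway catalog JSON; defaults to the packaged
#'   20-pathway catalog.
#' @param out_dir output directory (created); NULL to write nothing.
#' @param cfg a [classifier_config()].
#' @return List of class `pipeline_report`: `statuses`, `summaries`,
#'   `catalog_calls`, `counts_summary` (gene category counts), and
#'   `truth` when simulated.
#' @export
run_pipeline <- function(counts_path = NULL, design_path = NULL, sim = NULL,
                         catalog_path = regenpath_fixture("catalog.json"),
                         out_dir = NULL, cfg = classifier_config()) {
  from_files <- !is.null(counts_path) || !is.null(design_path)
  if (from_files && !is.null(sim))
    stop("supply either counts/design paths or a simulation config, not both")
  if (!from_files && is.null(sim))
    stop("supply counts/design paths or a simulation config")

  truth <- NULL
  if (from_files) {
    if (is.null(counts_path) || is.null(design_path))
      stop("both counts_path and design_path are required")
    m <- read_counts(counts_path, design_path)
  } else {
    res <- generate_dataset(sim, truth_config = cfg)
    m <- res$matrix
    truth <- res$truth
  }

  sf <- size_factors(m)
  sums <- summarize_groups(m, sf)
  statuses <- classify_all(m, cfg)
  cat_obj <- load_catalog(catalog_path)
  cc <- call_catalog(cat_obj, statuses)
  counts_summary <- write_gene_status(statuses, path = NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_group_summaries(sums, file.path(out_dir, "group_summaries.tsv"))
    fc <- statuses[, c("gene_id", "log2fc_P7", "log2fc_P28",
                       "p_concordance_P7", "p_rank_P7")]
    utils::write.table(fc, file.path(out_dir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_status(statuses, file.path(out_dir, "gene_status.tsv"))
    write_pathway_calls(cc, file.path(out_dir, "pathway_calls.json"),
                        file.path(out_dir, "pathway_summary.tsv"))
    report <- c(counts_summary, cc$summary,
                list(size_factors = as.list(sf)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(statuses = statuses, summaries = sums,
                 catalog_calls = cc, counts_summary = counts_summary,
                 size_factors = sf, truth = truth),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cs <- x$counts_summary
  s <- x$catalog_calls$summary
  cat(sprintf(paste0(
    "reverse pathway analysis report\n",
    "  genes: %d (%d pass abundance)\n",
    "  early upregulated: %d   late upregulated: %d   persistent: %d   late down: %d\n",
    "  pathways comprehensively upregulated: %d of %d called (%d in catalog)\n"),
    cs$n_genes, cs$n_pass_abundance, cs$n_early_up, cs$n_late_up,
    cs$n_persistent, cs$n_late_down,
    s$n_comprehensive, s$n_called, s$n_catalog))
  invisible(x)
}
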