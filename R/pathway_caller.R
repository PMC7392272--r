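#' Is a pathway node satisfied by the gene status table?
#'
#' A node represents a gene or a gene family with OR semantics: it is
#' satisfied when at least one member gene carries the requested
#' upregulation flag. Genes absent from the status table count as not
#' upregulated; a down-regulated member never satisfies a node.
#'
#' @param node one row of a `pathway_graph`'s `nodes` data.frame (or a
#'   list with a `members` character vector).
#' @param statuses data.frame with `gene_id`, `early_up`, `late_up`
#'   columns (e.g. from [classify_all()] or [reported_gene_calls()]).
#' @param mode `"early"` (P7 flag), `"late"` (P28 flag) or `"any"`
#'   (either, the "at P7 and/or P28" reading used for the headline call).
#' @return Logical scalar.
#' @export
node_satisfied <- function(node, statuses, mode = c("any", "early", "late")) {
  mode <- match.arg(mode)
  members <- if (is.data.frame(node)) node$members[[1]] else node$members
  idx <- match(members, statuses$gene_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(FALSE)
  e <- statuses$early_up[idx]
  l <- statuses$late_up[idx]
  switch(mode,
         early = any(e, na.rm = TRUE),
         late = any(l, na.rm = TRUE),
         any = any(e | l, na.rm = TRUE))
}

# annotate every node: both > early > late > down > unchanged > no_data
node_status_map <- function(g, statuses) {
  res <- vapply(seq_len(nrow(g$nodes)), function(i) {
    members <- g$nodes$members[[i]]
    idx <- match(members, statuses$gene_id)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return("no_data")
    e <- any(statuses$early_up[idx], na.rm = TRUE)
    l <- any(statuses$late_up[idx], na.rm = TRUE)
    d <- if ("late_down" %in% names(statuses))
      any(statuses$late_down[idx], na.rm = TRUE) else FALSE
    if (e && l) "both" else if (e) "early" else if (l) "late"
    else if (d) "down" else "unchanged"
  }, character(1))
  stats::setNames(res, g$nodes$node_id)
}

#' Decide whether a pathway is comprehensively upregulated
#'
#' A pathway is called comprehensively upregulated when at least one
#' complete directed chain from an initiator node to an effector node
#' consists entirely of satisfied nodes (satisfaction mode `"any"`: a node
#' counts if upregulated at P7 and/or P28). The search restricts the graph
#' to satisfied nodes and enumerates simple paths from each satisfied
#' initiator to each satisfied effector; chains are reported in
#' lexicographic order of their node-id sequences, up to `max_chains`.
#' Persistence annotations record whether every initiator (respectively
#' effector) participating in a satisfied chain is also upregulated late
#' (P28).
#'
#' @param g a `pathway_graph` from [load_pathway()].
#' @param statuses gene status table (see [node_satisfied()]).
#' @param max_chains cap on the number of reported chains (default 100).
#' @return List of class `pathway_call`: `pathway_id`, `comprehensive`,
#'   `satisfied_chains` (list of node-id vectors), `node_status` (named
#'   character vector: early/late/both/down/unchanged/no_data),
#'   `initiators_persistent`, `effectors_persistent`.
#' @export
comprehensive_call <- function(g, statuses, max_chains = 100L) {
  stopifnot(inherits(g, "pathway_graph"))
  inits <- g$nodes$node_id[g$nodes$role == "initiator"]
  effs <- g$nodes$node_id[g$nodes$role == "effector"]
  if (length(inits) == 0 || length(effs) == 0)
    stop("pathway '", g$pathway_id, "' needs at least one initiator and one effector")

  sat <- vapply(seq_len(nrow(g$nodes)),
                function(i) node_satisfied(g$nodes[i, ], statuses, "any"),
                logical(1))
  names(sat) <- g$nodes$node_id
  sat_nodes <- names(sat)[sat]

  chains <- list()
  if (length(sat_nodes) > 0 && any(inits %in% sat_nodes)) {
    ig <- igraph::induced_subgraph(pathway_igraph(g), sat_nodes)
    from <- sort(intersect(inits, sat_nodes))
    to <- sort(intersect(effs, sat_nodes))
    if (length(to) > 0) {
      for (f in from) {
        ps <- igraph::all_simple_paths(ig, from = f, to = to, mode = "out")
        chains <- c(chains, lapply(ps, function(p) igraph::as_ids(p)))
      }
      # an initiator that is itself an effector is a length-1 chain
      for (f in intersect(from, to)) chains <- c(chains, list(f))
    }
  }
  if (length(chains) > 0) {
    key <- vapply(chains, paste, "", collapse = "\r")
    chains <- chains[order(key)]
    chains <- chains[!duplicated(vapply(chains, paste, "", collapse = "\r"))]
    if (length(chains) > max_chains) chains <- chains[seq_len(max_chains)]
  }

  late_sat <- vapply(seq_len(nrow(g$nodes)),
                     function(i) node_satisfied(g$nodes[i, ], statuses, "late"),
                     logical(1))
  names(late_sat) <- g$nodes$node_id
  chain_nodes <- unique(unlist(chains))
  chain_inits <- intersect(inits, chain_nodes)
  chain_effs <- intersect(effs, chain_nodes)
  init_persist <- length(chain_inits) > 0 && all(late_sat[chain_inits])
  eff_persist <- length(chain_effs) > 0 && all(late_sat[chain_effs])

  structure(list(pathway_id = g$pathway_id,
                 comprehensive = length(chains) > 0,
                 satisfied_chains = chains,
                 node_status = node_status_map(g, statuses),
                 initiators_persistent = init_persist,
                 effectors_persistent = eff_persist),
            class = "pathway_call")
}

#' @export
print.pathway_call <- function(x, ...) {
  cat(sprintf("pathway_call '%s': %s (%d satisfied chain%s)\n",
              x$pathway_id,
              if (x$comprehensive) "comprehensively upregulated" else "not comprehensive",
              length(x$satisfied_chains),
              if (length(x$satisfied_chains) == 1) "" else "s"))
  invisible(x)
}

#' Call every pathway in a catalog
#'
#' Runs [comprehensive_call()] on each catalog entry with a detailed graph;
#' entries without one are reported as not called (the study provides no
#' node lists for them), never as "not upregulated".
#'
#' @param cat a `pathway_catalog` from [load_catalog()].
#' @param statuses gene status table.
#' @param max_chains per-pathway chain cap.
#' @return List of class `catalog_calls`: `table` (data.frame
#'   `pathway_id`, `called`, `comprehensive`, `n_satisfied_chains`,
#'   `initiators_persistent`, `effectors_persistent`), `calls` (named list
#'   of `pathway_call` objects), and `summary` (list `n_comprehensive`,
#'   `n_called`, `n_catalog`).
#' @export
call_catalog <- function(cat, statuses, max_chains = 100L) {
  stopifnot(inherits(cat, "pathway_catalog"))
  calls <- list()
  rows <- lapply(seq_len(nrow(cat$entries)), function(i) {
    e <- cat$entries[i, ]
    if (!e$has_detailed_graph) {
      return(data.frame(pathway_id = e$pathway_id, called = FALSE,
                        comprehensive = NA, n_satisfied_chains = NA_integer_,
                        initiators_persistent = NA, effectors_persistent = NA,
                        stringsAsFactors = FALSE))
    }
    cl <- comprehensive_call(load_pathway(e$graph_path), statuses, max_chains)
    calls[[e$pathway_id]] <<- cl
    data.frame(pathway_id = e$pathway_id, called = TRUE,
               comprehensive = cl$comprehensive,
               n_satisfied_chains = length(cl$satisfied_chains),
               initiators_persistent = cl$initiators_persistent,
               effectors_persistent = cl$effectors_persistent,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, calls = calls,
                 summary = list(
                   n_comprehensive = sum(tab$comprehensive, na.rm = TRUE),
                   n_called = sum(tab$called),
                   n_catalog = nrow(tab))),
            class = "catalog_calls")
}

#' @export
print.catalog_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("catalog_calls: %d comprehensively upregulated of %d called (%d in catalog)\n",
              s$n_comprehensive, s$n_called, s$n_catalog))
  invisible(x)
}

#' Write per-pathway calls to JSON and a catalog summary TSV
#'
#' @param cc a `catalog_calls` object.
#' @param json_path per-pathway call JSON output (NULL to skip).
#' @param tsv_path catalog summary TSV output (NULL to skip).
#' @return Invisibly, `cc`.
#' @export
write_pathway_calls <- function(cc, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(cc, "catalog_calls"))
  if (!is.null(json_path)) {
    obj <- lapply(cc$calls, function(cl) {
      list(pathway_id = cl$pathway_id, comprehensive = cl$comprehensive,
           satisfied_chains = cl$satisfied_chains,
           node_status = as.list(cl$node_status),
           initiators_persistent = cl$initiators_persistent,
           effectors_persistent = cl$effectors_persistent)
    })
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path))
    utils::write.table(cc$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(cc)
}
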