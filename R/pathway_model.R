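PATHWAY_ROLES <- c("initiator", "intermediate", "effector")

#' Path to a packaged pathway fixture
#'
#' The package ships JSON graphs for the five signaling pathways analyzed
#' in detail (MAPK, Hippo, cAMP, JAK-STAT, Ras), a 20-entry pathway
#' catalog, and the transcribed worked-example gene calls.
#'
#' @param name file name under the packaged `extdata/pathways` directory;
#'   with no argument, the directory itself.
#' @return Absolute file path.
#' @export
regenpath_fixture <- function(name = "") {
  p <- system.file("extdata", "pathways", name, package = "regenpath",
                   mustWork = FALSE)
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

#' Load and validate a pathway graph from JSON
#'
#' The dialect is a single JSON object with fields `pathway_id`, `name`,
#' `nodes` (list of objects with `node_id`, `label`, `role` one of
#' initiator/intermediate/effector, and a non-empty `members` gene list —
#' gene families have OR semantics), `edges` (list of `[from, to]` node-id
#' pairs) and optional `subpathways` (named node-id lists). Validation
#' rejects duplicate node IDs, dangling edges, empty member sets and
#' unknown roles, reporting a JSON-pointer-style location. Effectors not
#' reachable from any initiator are reported in the
#' `unreachable_effectors` attribute but are not an error (a fixture may
#' encode a deliberately broken chain).
#'
#' @param path path to a pathway JSON file.
#' @return List of class `pathway_graph`: `pathway_id`, `name`, `nodes`
#'   (data.frame `node_id`, `label`, `role` plus list-column `members`),
#'   `edges` (2-column character matrix), `subpathways` (named list).
#' @export
load_pathway <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("pathway_id", "name", "nodes", "edges")) {
    if (is.null(raw[[f]]))
      stop("pathway schema violation at /", f, ": field missing")
  }
  nodes <- raw$nodes
  if (length(nodes) == 0) stop("pathway schema violation at /nodes: empty")
  parse_node <- function(i) {
    nd <- nodes[[i]]
    ptr <- paste0("/nodes/", i - 1)
    for (f in c("node_id", "label", "role", "members"))
      if (is.null(nd[[f]]))
        stop("pathway schema violation at ", ptr, "/", f, ": field missing")
    if (!nd$role %in% PATHWAY_ROLES)
      stop("pathway schema violation at ", ptr, "/role: '", nd$role,
           "' is not one of ", paste(PATHWAY_ROLES, collapse = "/"))
    members <- unlist(nd$members)
    if (length(members) == 0)
      stop("pathway schema violation at ", ptr, "/members: empty member set")
    list(node_id = nd$node_id, label = nd$label, role = nd$role,
         members = as.character(members),
         annotation = if (is.null(nd$annotation)) NA_character_ else nd$annotation)
  }
  parsed <- lapply(seq_along(nodes), parse_node)
  ids <- vapply(parsed, `[[`, "", "node_id")
  if (anyDuplicated(ids)) {
    i <- which(duplicated(ids))[1]
    stop("pathway schema violation at /nodes/", i - 1,
         "/node_id: duplicate node ID '", ids[i], "'")
  }
  node_df <- data.frame(node_id = ids,
                        label = vapply(parsed, `[[`, "", "label"),
                        role = vapply(parsed, `[[`, "", "role"),
                        annotation = vapply(parsed, `[[`, "", "annotation"),
                        stringsAsFactors = FALSE)
  node_df$members <- lapply(parsed, `[[`, "members")

  edges <- raw$edges
  em <- matrix(character(0), ncol = 2,
               dimnames = list(NULL, c("from", "to")))
  if (length(edges) > 0) {
    for (i in seq_along(edges)) {
      e <- unlist(edges[[i]])
      if (length(e) != 2)
        stop("pathway schema violation at /edges/", i - 1,
             ": edge must be a [from, to] pair")
      for (k in 1:2)
        if (!e[k] %in% ids)
          stop("pathway schema violation at /edges/", i - 1, "/", k - 1,
               ": unknown node '", e[k], "'")
    }
    em <- do.call(rbind, lapply(edges, function(e) unlist(e)[1:2]))
    colnames(em) <- c("from", "to")
  }

  subp <- raw$subpathways
  subpathways <- list()
  if (!is.null(subp)) {
    for (nm in names(subp)) {
      v <- unlist(subp[[nm]])
      unknown <- setdiff(v, ids)
      if (length(unknown) > 0)
        stop("pathway schema violation at /subpathways/", nm,
             ": unknown node '", unknown[1], "'")
      subpathways[[nm]] <- as.character(v)
    }
  }

  if (!any(node_df$role == "initiator"))
    stop("pathway '", raw$pathway_id, "' has no initiator node")
  if (!any(node_df$role == "effector"))
    stop("pathway '", raw$pathway_id, "' has no effector node")

  g <- structure(list(pathway_id = raw$pathway_id, name = raw$name,
                      nodes = node_df, edges = em,
                      subpathways = subpathways),
                 class = "pathway_graph")
  attr(g, "unreachable_effectors") <- unreachable_effectors(g)
  g
}

# effectors with no directed path from any initiator (reported, not enforced)
unreachable_effectors <- function(g) {
  ig <- pathway_igraph(g)
  inits <- g$nodes$node_id[g$nodes$role == "initiator"]
  effs <- g$nodes$node_id[g$nodes$role == "effector"]
  if (length(effs) == 0 || length(inits) == 0) return(effs)
  d <- igraph::distances(ig, v = inits, to = effs, mode = "out")
  effs[apply(is.infinite(d), 2, all)]
}

pathway_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes$node_id, stringsAsFactors = FALSE))
}

#' Serialize a pathway graph back to JSON
#'
#' `load_pathway(write_pathway(g, f))` is structurally identical to `g`
#' (node, edge and subpathway order preserved as written).
#'
#' @param g a `pathway_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pathway <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    nd <- list(node_id = g$nodes$node_id[i], label = g$nodes$label[i],
               role = g$nodes$role[i], members = g$nodes$members[[i]])
    if (!is.na(g$nodes$annotation[i])) nd$annotation <- g$nodes$annotation[i]
    nd
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) unname(g$edges[i, ]))
  obj <- list(pathway_id = g$pathway_id, name = g$name, nodes = nodes,
              edges = edges)
  if (length(g$subpathways) > 0) obj$subpathways <- g$subpathways
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d nodes, %d edges, %d subpathways\n",
              x$pathway_id, x$name, nrow(x$nodes), nrow(x$edges),
              length(x$subpathways)))
  invisible(x)
}

#' Load and validate a pathway catalog from JSON
#'
#' A catalog is `{"entries": [{"pathway_id", "name", "graph_file"|null},
#' ...]}`; `graph_file` is resolved relative to the catalog's directory and
#' must exist when non-null. The packaged catalog holds the 20 candidate
#' cell-cycle / cell-fate signaling pathways, 5 of which carry detailed
#' graphs.
#'
#' @param path path to a catalog JSON file.
#' @return List of class `pathway_catalog`: `entries` (data.frame
#'   `pathway_id`, `name`, `has_detailed_graph`, `graph_path`) and
#'   `metadata` (list, possibly empty).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- raw$entries
  if (is.null(entries) || length(entries) == 0)
    stop("catalog must contain a non-empty 'entries' list")
  base <- dirname(normalizePath(path))
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.null(e$pathway_id) || is.null(e$name))
      stop("catalog entry ", i, " is missing pathway_id or name")
    gf <- e$graph_file
    gp <- NA_character_
    if (!is.null(gf)) {
      gp <- file.path(base, gf)
      if (!file.exists(gp))
        stop("catalog entry '", e$pathway_id,
             "' references missing graph file: ", gf)
    }
    data.frame(pathway_id = e$pathway_id, name = e$name,
               has_detailed_graph = !is.null(gf), graph_path = gp,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$pathway_id))
    stop("duplicate pathway_id in catalog: ",
         df$pathway_id[duplicated(df$pathway_id)][1])
  structure(list(entries = df,
                 metadata = if (is.null(raw$metadata)) list() else raw$metadata),
            class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("pathway_catalog: %d entries, %d with detailed graphs\n",
              nrow(x$entries), sum(x$entries$has_detailed_graph)))
  invisible(x)
}

#' Worked-example gene statuses transcribed from the reported pathway calls
#'
#' Returns the per-gene early/late/down flags for the genes named in the
#' five detailed pathway descriptions, as the study reported them
#' (early-postnatal red boxes, late-postnatal red text, down-regulated blue
#' text, and the explicitly unchanged YAP1/WWTR1 node). Used by the worked
#' example that re-derives "5 of 20 pathways comprehensively upregulated"
#' from graph traversal alone.
#'
#' @return data.frame compatible with the status table consumed by
#'   [comprehensive_call()]: `gene_id`, `passes_abundance`, `early_up`,
#'   `late_up`, `late_down`.
#' @export
reported_gene_calls <- function() {
  tab <- utils::read.delim(regenpath_fixture("reported_gene_calls.tsv"),
                           stringsAsFactors = FALSE)
  tab$passes_abundance <- as.logical(tab$passes_abundance)
  tab$early_up <- as.logical(tab$early_up)
  tab$late_up <- as.logical(tab$late_up)
  tab$late_down <- as.logical(tab$late_down)
  tab
}
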