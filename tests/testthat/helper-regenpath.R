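# shared builders for the test suite; all fixtures are constructed in code

# the five-group study design (CTL P1/P7/P28, MI P7/P28), nrep replicates
full_design <- function(nrep = 3) {
  groups <- rbind(c("CTL", "P1"), c("CTL", "P7"), c("CTL", "P28"),
                  c("MI", "P7"), c("MI", "P28"))
  data.frame(
    sample_id = as.vector(t(outer(paste(groups[, 1], groups[, 2], sep = "_"),
                                  seq_len(nrep), paste, sep = "_"))),
    condition = rep(groups[, 1], each = nrep),
    timepoint = rep(groups[, 2], each = nrep),
    replicate = rep(seq_len(nrep), times = 5),
    stringsAsFactors = FALSE)
}

# count matrix from a plain matrix plus the full design
make_cm <- function(counts, nrep = 3) {
  d <- full_design(nrep)
  colnames(counts) <- d$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  count_matrix(counts, d)
}

# random overdispersed matrix over the full design
rand_cm <- function(n_genes = 30, nrep = 3, seed = 1) {
  set.seed(seed)
  mu <- stats::rlnorm(n_genes, log(300), 0.8)
  counts <- matrix(stats::rnbinom(n_genes * 5 * nrep, mu = rep(mu, 5 * nrep),
                                  size = 10),
                   nrow = n_genes)
  make_cm(counts, nrep)
}

# write a tiny pathway JSON from parallel vectors; returns the path
write_pathway_json <- function(path, pathway_id, node_ids, roles, members,
                               edges, labels = node_ids, subpathways = NULL) {
  nodes <- lapply(seq_along(node_ids), function(i)
    list(node_id = node_ids[i], label = labels[i], role = roles[i],
         members = as.list(members[[i]])))
  obj <- list(pathway_id = pathway_id, name = pathway_id, nodes = nodes,
              edges = lapply(edges, as.list))
  if (!is.null(subpathways)) obj$subpathways <- subpathways
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  path
}

# status table from flag vectors
status_table <- function(early = character(0), late = character(0),
                         down = character(0)) {
  ids <- unique(c(early, late, down))
  data.frame(gene_id = ids,
             passes_abundance = rep(TRUE, length(ids)),
             early_up = ids %in% early,
             late_up = ids %in% late,
             late_down = ids %in% down,
             stringsAsFactors = FALSE)
}

# independent brute-force oracle for the comprehensive call: exhaustive
# recursion over the raw edge list, no graph library involved
brute_force_comprehensive <- function(g, statuses) {
  sat <- vapply(seq_len(nrow(g$nodes)), function(i) {
    memb <- g$nodes$members[[i]]
    idx <- match(memb, statuses$gene_id)
    idx <- idx[!is.na(idx)]
    length(idx) > 0 &&
      any(statuses$early_up[idx] | statuses$late_up[idx], na.rm = TRUE)
  }, logical(1))
  names(sat) <- g$nodes$node_id
  inits <- g$nodes$node_id[g$nodes$role == "initiator" & sat]
  effs <- g$nodes$node_id[g$nodes$role == "effector" & sat]
  if (length(inits) == 0 || length(effs) == 0) return(FALSE)
  walk <- function(node, seen) {
    if (node %in% effs) return(TRUE)
    nxt <- g$edges[g$edges[, "from"] == node, "to"]
    for (v in nxt) {
      if (!sat[v] || v %in% seen) next
      if (walk(v, c(seen, v))) return(TRUE)
    }
    FALSE
  }
  any(vapply(inits, function(f) walk(f, f), logical(1)))
}

# random small DAG pathway graph (topological edge direction, so acyclic)
rand_dag_pathway <- function(n_nodes = 8, seed = 1, p_edge = 0.35) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  roles <- rep("intermediate", n_nodes)
  roles[seq_len(max(1, rbinom(1, 2, 0.5) + 1))] <- "initiator"
  n_eff <- max(1, rbinom(1, 2, 0.5) + 1)
  roles[(n_nodes - n_eff + 1):n_nodes] <- "effector"
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) edges <- c(edges, list(c(ids[i], ids[j])))
    }
  }
  if (length(edges) == 0) edges <- list(c(ids[1], ids[n_nodes]))
  f <- tempfile(fileext = ".json")
  write_pathway_json(f, "random", ids, roles,
                     members = as.list(paste0(ids, "_gene")), edges = edges)
  load_pathway(f)
}

fixture_names <- c("mapk.json", "hippo.json", "camp.json",
                   "jak_stat.json", "ras.json")
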