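chain3 <- function() {
  f <- write_pathway_json(tempfile(fileext = ".json"), "chain3",
                          c("a", "b", "c"),
                          c("initiator", "intermediate", "effector"),
                          list("GA", c("GB1", "GB2"), "GC"),
                          list(c("a", "b"), c("b", "c")))
  load_pathway(f)
}

test_that("node satisfaction uses OR semantics over family members", {
  g <- chain3()
  node_b <- g$nodes[2, ]
  st <- status_table(early = "GB1")
  expect_true(node_satisfied(node_b, st, "any"))
  expect_true(node_satisfied(node_b, st, "early"))
  expect_false(node_satisfied(node_b, st, "late"))
  expect_true(node_satisfied(node_b, status_table(late = "GB2"), "any"))
  # absent members count as not upregulated
  expect_false(node_satisfied(node_b, status_table(early = "OTHER"), "any"))
  # down-regulation never satisfies
  expect_false(node_satisfied(node_b, status_table(down = "GB1"), "any"))
})

test_that("a chain is comprehensive only when every node is satisfied", {
  g <- chain3()
  full <- comprehensive_call(g, status_table(early = c("GA", "GB2", "GC")))
  expect_true(full$comprehensive)
  expect_equal(full$satisfied_chains, list(c("a", "b", "c")))

  broken <- comprehensive_call(g, status_table(early = c("GA", "GC")))
  expect_false(broken$comprehensive)
  expect_equal(length(broken$satisfied_chains), 0)
  # GB1/GB2 are absent from the status table entirely: no_data
  expect_equal(unname(broken$node_status[c("a", "b", "c")]),
               c("early", "no_data", "early"))

  none <- comprehensive_call(g, status_table())
  expect_false(none$comprehensive)
})

test_that("persistence flags track late satisfaction on satisfied chains", {
  g <- chain3()
  st <- status_table(early = c("GA", "GB1", "GC"), late = c("GA", "GC"))
  cl <- comprehensive_call(g, st)
  expect_true(cl$initiators_persistent)
  expect_true(cl$effectors_persistent)
  expect_equal(unname(cl$node_status[c("a", "b", "c")]),
               c("both", "early", "both"))

  st2 <- status_table(early = c("GA", "GB1", "GC"), late = "GA")
  cl2 <- comprehensive_call(g, st2)
  expect_true(cl2$initiators_persistent)
  expect_false(cl2$effectors_persistent)
})

test_that("satisfaction is monotone and local", {
  set.seed(31)
  for (i in 1:15) {
    g <- rand_dag_pathway(n_nodes = sample(5:9, 1), seed = i)
    genes <- unlist(g$nodes$members)
    up <- sample(genes, size = rbinom(1, length(genes), 0.5))
    st <- status_table(early = up)
    base_call <- comprehensive_call(g, st)$comprehensive
    # adding upregulated genes never retracts a comprehensive call
    more <- status_table(early = unique(c(up, sample(genes, 2))))
    if (base_call) expect_true(comprehensive_call(g, more)$comprehensive)
    # removing genes never creates one
    fewer <- status_table(early = up[-seq_len(min(1, length(up)))])
    if (!base_call) expect_false(comprehensive_call(g, fewer)$comprehensive)
    # statuses of unrelated genes never change the call
    noisy <- rbind(st, status_table(early = c("ZZZ1", "ZZZ2")))
    expect_equal(comprehensive_call(g, noisy)$comprehensive, base_call)
  }
})

test_that("the caller matches brute-force path enumeration on small DAGs", {
  set.seed(77)
  for (i in 1:25) {
    g <- rand_dag_pathway(n_nodes = sample(4:12, 1), seed = 1000 + i)
    genes <- unlist(g$nodes$members)
    st <- status_table(early = sample(genes, rbinom(1, length(genes), 0.6)))
    expect_equal(comprehensive_call(g, st)$comprehensive,
                 brute_force_comprehensive(g, st),
                 info = paste("dag", i))
  }
})

test_that("node and edge declaration order does not change the call", {
  g <- load_pathway(regenpath_fixture("jak_stat.json"))
  st <- reported_gene_calls()
  ref <- comprehensive_call(g, st)
  set.seed(5)
  perm_nodes <- sample(nrow(g$nodes))
  perm_edges <- sample(nrow(g$edges))
  g2 <- g
  g2$nodes <- g$nodes[perm_nodes, ]
  g2$edges <- g$edges[perm_edges, , drop = FALSE]
  f <- tempfile(fileext = ".json")
  write_pathway(g2, f)
  shuffled <- comprehensive_call(load_pathway(f), st)
  expect_equal(shuffled$comprehensive, ref$comprehensive)
  expect_equal(shuffled$satisfied_chains, ref$satisfied_chains)
  expect_equal(shuffled$node_status[sort(names(shuffled$node_status))],
               ref$node_status[sort(names(ref$node_status))])
})

test_that("cycles terminate and an initiator-effector node forms a chain", {
  f <- write_pathway_json(tempfile(fileext = ".json"), "cyc",
                          c("a", "b", "c"),
                          c("initiator", "intermediate", "effector"),
                          list("GA", "GB", "GC"),
                          list(c("a", "b"), c("b", "a"), c("b", "c")))
  g <- load_pathway(f)
  cl <- comprehensive_call(g, status_table(early = c("GA", "GB", "GC")))
  expect_true(cl$comprehensive)
  expect_true(any(vapply(cl$satisfied_chains, identical, logical(1),
                         c("a", "b", "c"))))

  # a graph without an effector is rejected at load time
  f2 <- write_pathway_json(tempfile(fileext = ".json"), "solo",
                           "a", "initiator", list("GA"), list())
  expect_error(load_pathway(f2), "effector")
})

test_that("catalog calls separate not-called from not-comprehensive", {
  cat_obj <- load_catalog(regenpath_fixture("catalog.json"))
  cc <- call_catalog(cat_obj, status_table())   # empty status table
  expect_equal(cc$summary$n_comprehensive, 0)
  expect_equal(cc$summary$n_called, 5)
  expect_equal(cc$summary$n_catalog, 20)
  expect_true(all(is.na(cc$table$comprehensive[!cc$table$called])))
  expect_true(all(!cc$table$comprehensive[cc$table$called]))
})
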