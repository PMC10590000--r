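test_that("graph assembly annotates nodes and surfaces cycles", {
  phe <- data.table::data.table(outcome = c("A", "B", "C"),
                                hr = c(2, 3, 4), n_cases = c(10L, 20L, 30L),
                                n_cases_exposed = c(5L, 10L, 15L))
  pairs <- data.table::data.table(d1 = c("A", "B", "A"), d2 = c("B", "C", "C"),
                                  or = c(2, 3, 4), n_both = c(5L, 6L, 7L),
                                  binom_p = 1e-4, logit_p = 1e-4)
  g <- assemble_graph(phe, pairs)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$nodes$hr[g$nodes$category == "B"], 3)

  expect_equal(nrow(assemble_graph(phe, pairs[0, ])$edges), 0L)

  cyc <- data.table::data.table(d1 = c("A", "B"), d2 = c("B", "A"),
                                or = 2, n_both = 5L, binom_p = 1, logit_p = 1)
  expect_message(g2 <- assemble_graph(phe, cyc), "cycle")
  expect_equal(nrow(g2$edges), 2L)  # both orientations retained

  expect_error(assemble_graph(phe[1:2], pairs), "without a PheWAS annotation")
})

test_that("shortcut edges are pruned, cycles exempted, pruning idempotent", {
  phe <- data.table::data.table(outcome = LETTERS[1:4], hr = 2,
                                n_cases = 10L, n_cases_exposed = 5L)
  tri <- data.table::data.table(d1 = c("A", "B", "A"), d2 = c("B", "C", "C"),
                                or = 2, n_both = 5L, binom_p = 1e-4,
                                logit_p = 1e-4)
  g <- transitive_prune(assemble_graph(phe, tri))
  pruned <- g$edges[g$edges$pruned]
  expect_equal(nrow(pruned), 1L)
  expect_equal(pruned$d1, "A")
  expect_equal(pruned$d2, "C")  # the D1 -> D3 line is deleted
  expect_equal(nrow(active_edges(g)), 2L)
  # pruned edges are retained in the table, flagged
  expect_equal(nrow(g$edges), 3L)
  # idempotence
  expect_identical(transitive_prune(g)$edges, g$edges)

  # edges on a directed cycle are never pruned
  cyc <- data.table::data.table(d1 = c("A", "B", "C", "A"),
                                d2 = c("B", "C", "A", "D"),
                                or = 2, n_both = 5L, binom_p = 1, logit_p = 1)
  g2 <- suppressMessages(transitive_prune(assemble_graph(phe, cyc)))
  expect_false(any(g2$edges$pruned))
})

test_that("pruning equals brute-force transitive reduction on random DAGs", {
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(4:10, 1)
    adj <- random_dag(k)
    if (!any(adj)) next
    g <- transitive_prune(graph_from_adj(adj))
    got <- adj_from_graph(g)
    oracle <- transitive_reduction_oracle(adj)
    expect_identical(got, oracle, info = sprintf("rep %d", rep))
    # reachability preserved exactly
    expect_identical(closure_oracle(got) > 0, closure_oracle(adj) > 0)
    # idempotent
    expect_identical(adj_from_graph(transitive_prune(g)), got)
  }
})

test_that("layering labels original, intermediary and terminal diseases", {
  phe <- data.table::data.table(outcome = LETTERS[1:5], hr = 2,
                                n_cases = 10L, n_cases_exposed = 5L)
  chain <- data.table::data.table(d1 = c("A", "B"), d2 = c("B", "C"),
                                  or = 2, n_both = 5L, binom_p = 1e-4,
                                  logit_p = 1e-4)
  lay <- layer_nodes(assemble_graph(phe[1:3], chain))
  expect_equal(lay$layer[lay$category == "A"], "original")
  expect_equal(lay$layer[lay$category == "B"], "intermediary")
  expect_equal(lay$layer[lay$category == "C"], "terminal")
  expect_equal(lay$n_descendants[lay$category == "B"], 1L)
  expect_equal(lay$depth, c(0, 1, 2))

  # isolated node: simultaneously source and sink
  iso <- layer_nodes(assemble_graph(phe[c(1, 2, 4)], chain[1], nodes = "D"))
  expect_equal(iso$layer[iso$category == "D"], "original-terminal")

  # star: A has three descendants
  star <- data.table::data.table(d1 = "A", d2 = c("B", "C", "D"),
                                 or = 2, n_both = 5L, binom_p = 1e-4,
                                 logit_p = 1e-4)
  ls <- layer_nodes(assemble_graph(phe[1:4], star))
  expect_equal(ls$n_descendants[ls$category == "A"], 3L)
  expect_equal(ls$n_direct[ls$category == "A"], 3L)
})

test_that("GraphML export round-trips, handles empty graphs and bad formats", {
  phe <- data.table::data.table(outcome = c("A", "B", "Cœur"),
                                hr = c(1.5, 2.25, 3), n_cases = c(3L, 4L, 5L),
                                n_cases_exposed = c(1L, 2L, 3L))
  pairs <- data.table::data.table(d1 = c("A", "B"), d2 = c("B", "Cœur"),
                                  or = c(2.5, 3.75), n_both = c(5L, 6L),
                                  binom_p = c(1e-4, 2e-5),
                                  logit_p = c(3e-4, 4e-6))
  g <- assemble_graph(phe, pairs)
  d <- withr::local_tempdir()
  files <- export_graph(g, d)
  expect_true(file.exists(file.path(d, "graph.graphml")))
  g2 <- import_graphml(file.path(d, "graph.graphml"))
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)  # non-ASCII category preserved

  # export is byte-stable
  d2 <- withr::local_tempdir()
  export_graph(g, d2)
  expect_identical(readBin(file.path(d, "graph.graphml"), "raw", 1e6),
                   readBin(file.path(d2, "graph.graphml"), "raw", 1e6))

  empty <- structure(list(
    nodes = data.table::data.table(category = character(), hr = numeric(),
                                   n_cases = integer()),
    edges = data.table::data.table(d1 = character(), d2 = character(),
                                   or = numeric(), n_both = integer(),
                                   binom_p = numeric(), logit_p = numeric(),
                                   pruned = logical())),
    class = "trajectory_graph")
  export_graph(empty, d2)
  e0 <- import_graphml(file.path(d2, "graph.graphml"))
  expect_equal(nrow(e0$nodes), 0L)

  expect_error(export_graph(g, d, formats = "dot"), "unknown format")
})
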