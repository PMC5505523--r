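test_that("maximal cliques are found, size-bounded and deterministic", {
  # triangle a-b-c with pendant d-a
  net <- make_weighted_network(c("a", "a", "b", "a"),
                               c("b", "c", "c", "d"), 1)
  expect_identical(maximal_cliques(net, min_size = 3),
                   list(c("a", "b", "c")))

  # K5 yields the single 5-clique, not its sub-cliques
  idx <- utils::combn(letters[1:5], 2L)
  k5 <- make_weighted_network(idx[1L, ], idx[2L, ], 1)
  expect_identical(maximal_cliques(k5, min_size = 4, max_size = 20),
                   list(letters[1:5]))

  # empty graph
  empty <- suppressWarnings(build_base_network(
    data.frame(gene_a = "a", gene_b = "b", combined_score = 0.1),
    0.8, c("a", "b")))
  expect_identical(maximal_cliques(empty), list())

  # cliques above max_size are discarded, not truncated
  expect_identical(maximal_cliques(k5, min_size = 3, max_size = 4), list())
})

test_that("clique enumeration matches the exhaustive subset oracle", {
  set.seed(55)
  for (rep in 1:30) {
    g <- rand_graph_edges(12, 0.5)
    net <- suppressWarnings(build_base_network(g$edges, 0, g$nodes))
    for (bounds in list(c(1, 14), c(3, 5))) {
      expect_identical(
        maximal_cliques(net, bounds[1], bounds[2]),
        bf_max_cliques(net$nodes, g$edges, bounds[1], bounds[2]))
    }
  }
})

test_that("WID equals the mean edge weight of a clique", {
  # uniform weights: the score is exactly the weight
  idx <- utils::combn(letters[1:4], 2L)
  net <- make_weighted_network(idx[1L, ], idx[2L, ], 0.8)
  expect_equal(wid(letters[1:4], net), 0.8)

  # size-3 clique with weights 1.0, 0.5, 0.0
  tri <- make_weighted_network(c("a", "a", "b"), c("b", "c", "c"),
                               c(1, 0.5, 0))
  expect_equal(wid(c("a", "b", "c"), tri), 0.5)

  # random size-6 clique: mean of its 15 edge weights
  set.seed(6)
  idx6 <- utils::combn(letters[1:6], 2L)
  w6 <- runif(15)
  net6 <- make_weighted_network(idx6[1L, ], idx6[2L, ], w6)
  expect_equal(wid(letters[1:6], net6), mean(w6), tolerance = 1e-12)

  expect_error(wid("a", net6), "2 genes")
})

test_that("inter-connectivity follows the cross-density formulas", {
  # no cross edges -> 0
  net0 <- make_weighted_network(c("a", "x"), c("b", "y"), 1)
  expect_equal(interconnectivity(c("a", "b"), c("x", "y"), net0), 0)

  # complete crossing at weight w, no overlap -> w under the geometric
  # mean and w^2 under the literal product
  g1 <- c("a", "b"); g2 <- c("x", "y")
  cross <- expand.grid(g1, g2, stringsAsFactors = FALSE)
  netw <- make_weighted_network(cross[[1]], cross[[2]], 0.6)
  expect_equal(interconnectivity(g1, g2, netw), 0.6, tolerance = 1e-12)
  expect_equal(interconnectivity(g1, g2, netw, mode = "product"), 0.36,
               tolerance = 1e-12)

  # nested gene sets -> 1 by convention
  expect_equal(interconnectivity(c("a", "b"), c("a", "b", "x"), netw), 1)

  # random 5+5 cliques sharing 2 genes vs a hand-computed double sum
  set.seed(14)
  k1 <- c("s1", "s2", "u1", "u2", "u3")
  k2 <- c("s1", "s2", "v1", "v2", "v3")
  all_genes <- union(k1, k2)
  idx <- utils::combn(all_genes, 2L)
  w <- runif(ncol(idx))
  net <- make_weighted_network(idx[1L, ], idx[2L, ], w)
  wmat <- matrix(0, 8, 8, dimnames = list(all_genes, all_genes))
  for (r in seq_len(ncol(idx))) {
    wmat[idx[1L, r], idx[2L, r]] <- w[r]
    wmat[idx[2L, r], idx[1L, r]] <- w[r]
  }
  d1 <- setdiff(k1, k2); d2 <- setdiff(k2, k1)
  m1 <- sum(wmat[d1, k2]) / (length(d1) * length(k2))
  m2 <- sum(wmat[d2, k1]) / (length(d2) * length(k1))
  expect_equal(interconnectivity(k1, k2, net), sqrt(m1 * m2),
               tolerance = 1e-12)
  expect_equal(interconnectivity(k1, k2, net, mode = "product"), m1 * m2,
               tolerance = 1e-12)
})

test_that("clique merging agglomerates to the expected modules", {
  # two cliques with zero inter-connectivity stay separate
  idxa <- utils::combn(c("a1", "a2", "a3"), 2L)
  idxb <- utils::combn(c("b1", "b2", "b3"), 2L)
  net <- make_weighted_network(c(idxa[1L, ], idxb[1L, ]),
                               c(idxa[2L, ], idxb[2L, ]), 1)
  mods <- merge_cliques(list(c("a1", "a2", "a3"), c("b1", "b2", "b3")),
                        net)
  expect_length(mods, 2L)

  # heavily overlapping cliques with unit cross weights merge into one
  k1 <- c("a", "b", "c", "d")
  k2 <- c("b", "c", "d", "e")
  idx <- utils::combn(union(k1, k2), 2L)
  net2 <- make_weighted_network(idx[1L, ], idx[2L, ], 1)
  mods2 <- merge_cliques(list(k1, k2), net2)
  expect_length(mods2, 1L)
  expect_identical(mods2[[1]]$genes, c("a", "b", "c", "d", "e"))
  expect_identical(sort(mods2[[1]]$source_cliques), 1:2)
  expect_equal(mods2[[1]]$wid, 1)
})

test_that("merging is a fixed point independent of processing order", {
  set.seed(91)
  for (rep in 1:15) {
    g <- rand_graph_edges(14, 0.55)
    net <- suppressWarnings(build_base_network(g$edges, 0, g$nodes))
    net$edges$weight <- runif(nrow(net$edges), 0.3, 1)
    cliques <- maximal_cliques(net, min_size = 3, max_size = 14)
    if (length(cliques) < 2) next
    mods <- merge_cliques(cliques, net, merge_threshold = 0.5)
    got <- lapply(mods, `[[`, "genes")
    got <- got[order(vapply(got, paste, "", collapse = "\r"))]
    expect_identical(got,
                     oracle_merge_gene_sets(cliques, net, 0.5))
    # permutation invariance of the input clique list
    perm <- sample(length(cliques))
    mods_p <- merge_cliques(cliques[perm], net, merge_threshold = 0.5)
    got_p <- lapply(mods_p, `[[`, "genes")
    expect_identical(got_p, lapply(mods, `[[`, "genes"))
  }
})

test_that("raising the merge threshold never decreases the module count", {
  set.seed(17)
  g <- rand_graph_edges(14, 0.6)
  net <- suppressWarnings(build_base_network(g$edges, 0, g$nodes))
  net$edges$weight <- runif(nrow(net$edges), 0.3, 1)
  cliques <- maximal_cliques(net, min_size = 3, max_size = 14)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(thr)
    length(merge_cliques(cliques, net, merge_threshold = thr)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("every module induces a connected destination subgraph", {
  sim <- simulate_ppi_expression(n_genes = 100, n_planted_modules = 2,
                                 rho_control = 0.8,
                                 background_edge_prob = 0.05, seed = 33)
  for (cond in c("expr_case", "expr_control")) {
    net <- significance_filter(reweight_network(
      build_base_network(sim$edges, 0.8, rownames(sim[[cond]])),
      sim[[cond]]), 0.05)
    cliques <- maximal_cliques(net)
    mods <- merge_cliques(cliques, net, expr = sim[[cond]])
    for (m in mods) {
      sub <- net$edges[net$edges$gene_a %in% m$genes &
                         net$edges$gene_b %in% m$genes, ]
      g <- igraph::graph_from_data_frame(sub[, 1:2], directed = FALSE,
                                         vertices = m$genes)
      expect_true(igraph::is_connected(g))
      expect_true(m$wid >= 0 && m$wid <= 1)
      expect_true(m$dcc >= 0 && m$dcc <= 1)
    }
  }
})
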