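test_that("score threshold is inclusive and unprofiled genes drop out", {
  e <- data.frame(gene_a = c("g1", "g1", "g2"),
                  gene_b = c("g2", "g3", "g3"),
                  combined_score = c(0.9, 0.8, 0.7))
  net <- build_base_network(e, 0.8, c("g1", "g2", "g3"))
  expect_equal(nrow(net$edges), 2L)  # 0.8 retained, 0.7 dropped

  # g3 unprofiled: its edges vanish, g1 survives through the g1-g2 edge
  net2 <- build_base_network(e, 0.8, c("g1", "g2"))
  expect_identical(net2$nodes, c("g1", "g2"))
  expect_equal(nrow(net2$edges), 1L)

  expect_warning(build_base_network(e, 0.8, "g9"), "empty")
  expect_error(build_base_network(data.frame(gene_a = "a", gene_b = "b",
                                             combined_score = 1.2),
                                  0.8, c("a", "b")),
               "\\[0, 1\\]")
})

test_that("base network construction matches a set-comprehension oracle", {
  set.seed(31)
  for (rep in 1:5) {
    g <- rand_graph_edges(50, 0.15)
    g$edges$combined_score <- round(runif(nrow(g$edges)), 3)
    profiled <- sample(g$nodes, 35)
    thr <- 0.5
    net <- suppressWarnings(build_base_network(g$edges, thr, profiled))
    keep <- g$edges$combined_score >= thr &
      g$edges$gene_a %in% profiled & g$edges$gene_b %in% profiled
    expect_equal(nrow(net$edges), sum(keep))
    expect_identical(net$nodes,
                     sort(unique(c(g$edges$gene_a[keep],
                                   g$edges$gene_b[keep]))))
  }
})

test_that("re-weighting assigns the absolute Pearson correlation", {
  e <- data.frame(gene_a = c("a", "a", "a"), gene_b = c("b", "c", "d"),
                  combined_score = 1)
  expr <- rbind(a = c(1, 2, 3, 4),
                b = c(1, 2, 3, 4),          # identical -> weight 1
                c = -c(1, 2, 3, 4),         # anti-correlated -> weight 1
                d = c(1.1, 1.9, 3.2, 3.8))  # textbook PCC
  net <- reweight_network(build_base_network(e, 0.5, rownames(expr)), expr)
  w <- net$edges$weight[match(c("b", "c", "d"), net$edges$gene_b)]
  expect_equal(w[1], 1)
  expect_equal(w[2], 1)
  a <- expr["a", ]; d <- expr["d", ]
  pcc <- sum((a - mean(a)) * (d - mean(d))) /
    sqrt(sum((a - mean(a))^2) * sum((d - mean(d))^2))
  expect_equal(w[3], abs(pcc), tolerance = 1e-12)
})

test_that("re-weighting is symmetric in the edge orientation", {
  set.seed(8)
  expr <- matrix(rnorm(4 * 10), 4, dimnames = list(letters[1:4], NULL))
  e_ab <- data.frame(gene_a = "a", gene_b = "b", combined_score = 1)
  e_ba <- data.frame(gene_a = "b", gene_b = "a", combined_score = 1)
  w1 <- reweight_network(build_base_network(e_ab, 0.5, letters[1:4]),
                         expr)$edges$weight
  w2 <- reweight_network(build_base_network(e_ba, 0.5, letters[1:4]),
                         expr)$edges$weight
  expect_identical(w1, w2)
})

test_that("zero-variance genes yield weight 0 and p-value 1", {
  expr <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  e <- data.frame(gene_a = "a", gene_b = "b", combined_score = 1)
  expect_message(
    net <- reweight_network(build_base_network(e, 0.5, c("a", "b")), expr),
    "zero-variance")
  expect_equal(net$edges$weight, 0)
  expect_equal(net$edges$p_value, 1)
})

test_that("too few samples to test a correlation is an error", {
  expr <- rbind(a = c(1, 2), b = c(2, 1))
  e <- data.frame(gene_a = "a", gene_b = "b", combined_score = 1)
  expect_error(
    reweight_network(build_base_network(e, 0.5, c("a", "b")), expr),
    "samples")
})

test_that("edge p-values follow the one-sided t transform of |r|", {
  # r = 0.4, n = 18: p must equal the t survival value at df = 16
  n <- 18
  x <- scale(rnorm(n))[, 1]
  eps <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  r_target <- 0.4
  y <- r_target * x + sqrt(1 - r_target^2) * eps   # exact sample r = 0.4
  expr <- rbind(a = x, b = y)
  e <- data.frame(gene_a = "a", gene_b = "b", combined_score = 1)
  net <- reweight_network(build_base_network(e, 0.5, c("a", "b")), expr)
  expect_equal(net$edges$weight, 0.4, tolerance = 1e-10)
  p_oracle <- pt(0.4 * sqrt(16) / sqrt(1 - 0.16), df = 16,
                 lower.tail = FALSE)
  expect_equal(net$edges$p_value, p_oracle, tolerance = 1e-10)
  # keep/drop at alpha 0.05 decided by the oracle value
  kept <- nrow(significance_filter(net, 0.05)$edges) == 1L
  expect_identical(kept, p_oracle < 0.05)
})

test_that("destination edge set shrinks monotonically as alpha falls", {
  set.seed(19)
  sim <- simulate_ppi_expression(n_genes = 80, n_planted_modules = 2,
                                 background_edge_prob = 0.05,
                                 score_range = c(0.7, 1), seed = 19)
  net <- reweight_network(
    build_base_network(sim$edges, 0.8, rownames(sim$expr_case)),
    sim$expr_case, condition = "case")
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- vapply(alphas,
                   function(a) nrow(significance_filter(net, a)$edges), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("null edges survive the filter at twice the nominal level", {
  # the one-sided test is applied to |r|, so under rho = 0 the retention
  # probability at alpha is 2 * alpha
  set.seed(23)
  n_edge <- 3000
  expr <- matrix(rnorm(2 * n_edge * 18), ncol = 18)
  rownames(expr) <- sprintf("g%04d", seq_len(2 * n_edge))
  e <- data.frame(gene_a = rownames(expr)[seq_len(n_edge) * 2 - 1],
                  gene_b = rownames(expr)[seq_len(n_edge) * 2],
                  combined_score = 1)
  net <- reweight_network(build_base_network(e, 0.5, rownames(expr)), expr)
  frac <- nrow(significance_filter(net, 0.05)$edges) / n_edge
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n_edge))
})

test_that("planted intra-module edges survive the filter at rho = 0.9", {
  hits <- total <- 0
  for (s in 1:5) {
    sim <- simulate_ppi_expression(n_genes = 60, n_planted_modules = 2,
                                   rho_case = 0.9, seed = 200 + s)
    net <- significance_filter(reweight_network(
      build_base_network(sim$edges, 0.8, rownames(sim$expr_case)),
      sim$expr_case), 0.05)
    key <- paste(net$edges$gene_a, net$edges$gene_b)
    for (g in sim$ground_truth$planted_modules) {
      idx <- utils::combn(sort(g), 2L)
      hits <- hits + sum(paste(idx[1L, ], idx[2L, ]) %in% key)
      total <- total + ncol(idx)
    }
  }
  expect_gte(hits / total, 0.95)
})
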