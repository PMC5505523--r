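# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# ppi_network with explicit weights, bypassing correlation re-weighting
make_weighted_network <- function(gene_a, gene_b, weight,
                                  condition = NA_character_) {
  e <- data.frame(gene_a = pmin(gene_a, gene_b),
                  gene_b = pmax(gene_a, gene_b),
                  score = 1, weight = weight, p_value = 0,
                  stringsAsFactors = FALSE)
  attracmod:::new_ppi_network(e, condition)
}

rand_graph_edges <- function(n_nodes, p) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  idx <- utils::combn(n_nodes, 2L)
  keep <- stats::runif(ncol(idx)) < p
  list(nodes = nodes,
       edges = data.frame(gene_a = nodes[idx[1L, keep]],
                          gene_b = nodes[idx[2L, keep]],
                          combined_score = 1,
                          stringsAsFactors = FALSE))
}

# exhaustive maximal-clique enumeration by bitmask subset checking (n <= 14);
# returns the same representation as maximal_cliques(): sorted gene vectors
# ordered by decreasing size then lexicographically
bf_max_cliques <- function(nodes, edges, min_size = 1, max_size = Inf) {
  n <- length(nodes)
  stopifnot(n <= 14)
  adj <- integer(n)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$gene_a[r], nodes)
    j <- match(edges$gene_b[r], nodes)
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  masks <- seq_len(2L^n - 1L)
  complete <- rep(TRUE, length(masks))
  maximal <- rep(TRUE, length(masks))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    has_v <- bitwAnd(masks, bit) != 0L
    rest <- masks - bit * has_v
    # clique: every member adjacent to all other members
    complete <- complete &
      (!has_v | bitwAnd(adj[v], rest) == rest)
    # maximal: no outside vertex adjacent to the whole subset
    maximal <- maximal &
      (has_v | bitwAnd(adj[v], masks) != masks)
  }
  sizes <- rowSums(vapply(0:(n - 1L), function(b)
    bitwAnd(masks, bitwShiftL(1L, b)) != 0L, logical(length(masks))))
  hits <- which(complete & maximal & sizes >= min_size & sizes <= max_size)
  cl <- lapply(hits, function(m)
    sort(nodes[bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L]))
  key <- vapply(cl, paste, "", collapse = "\r")
  cl[order(-lengths(cl), key)]
}

# Welch statistic, Satterthwaite df and two-sided p from first principles
oracle_welch <- function(fa, fv) {
  A <- length(fa); V <- length(fv)
  sa2 <- sum((fa - mean(fa))^2) / (A - 1)
  sv2 <- sum((fv - mean(fv))^2) / (V - 1)
  t <- (mean(fa) - mean(fv)) / sqrt(sa2 / A + sv2 / V)
  w <- (sa2 / A + sv2 / V)^2 /
    (sa2^2 / (A^2 * (A - 1)) + sv2^2 / (V^2 * (V - 1)))
  list(t = t, w = w, p = 2 * stats::pt(abs(t), df = w, lower.tail = FALSE))
}

# step-up FDR adjustment written independently of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(p[o] * n / seq_len(n)))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# naive clique agglomeration to a fixed point in a caller-chosen order
oracle_merge_gene_sets <- function(cliques, network, thr,
                                   mode = "geometric") {
  groups <- lapply(cliques, list)
  repeat {
    merged <- FALSE
    ng <- length(groups)
    for (i in seq_len(ng - 1L)) {
      for (j in (i + 1L):ng) {
        hit <- any(vapply(groups[[i]], function(k1)
          any(vapply(groups[[j]], function(k2)
            interconnectivity(k1, k2, network, mode) >= thr, TRUE)), TRUE))
        if (hit) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sets <- lapply(groups, function(g) sort(unique(unlist(g))))
  sets[order(vapply(sets, paste, "", collapse = "\r"))]
}

# greedy one-to-one pairing written directly from the rule
oracle_pairing <- function(case_sets, control_sets, j_thr, min_size) {
  out <- NULL
  for (i in seq_along(case_sets)) for (j in seq_along(control_sets)) {
    a <- case_sets[[i]]; b <- control_sets[[j]]
    if (length(a) < min_size || length(b) < min_size) next
    jac <- length(intersect(a, b)) / length(union(a, b))
    if (jac >= j_thr)
      out <- rbind(out, data.frame(i = i, j = j, jac = jac,
                                   ka = sort(a)[1], kb = sort(b)[1]))
  }
  if (is.null(out)) return(out)
  out <- out[order(-out$jac, out$ka, out$kb), ]
  keep <- logical(nrow(out)); uc <- uk <- integer(0)
  for (r in seq_len(nrow(out))) {
    if (out$i[r] %in% uc || out$j[r] %in% uk) next
    keep[r] <- TRUE; uc <- c(uc, out$i[r]); uk <- c(uk, out$j[r])
  }
  out[keep, c("i", "j", "jac")]
}
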