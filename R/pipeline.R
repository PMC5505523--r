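#' Fit the attractor-module pipeline to a two-condition data set
#'
#' Runs the full module-discovery procedure: (1) confidence-filter the
#' interaction list and restrict it to profiled genes
#' ([build_base_network()]); (2) re-weight the network per condition by the
#' absolute Pearson correlation of each edge's genes and keep edges with a
#' significant correlation ([reweight_network()], [significance_filter()]);
#' (3) mine size-bounded maximal cliques and merge inter-connected cliques
#' into modules ([maximal_cliques()], [merge_cliques()]); (4) pair case and
#' control modules by Jaccard similarity of gene composition
#' ([pair_modules()]); (5) score each pair with the GSEA-ANOVA statistic —
#' a Welch t-test of the pair's genes' per-gene ANOVA F-statistics against
#' all remaining genes — and flag attractor modules at a
#' Benjamini-Hochberg FDR threshold ([gene_f_statistics()],
#' [attract_test()], [call_attractors()]). The tested gene set of a pair is
#' the union of its case and control modules' genes.
#'
#' The analysis is fully deterministic: identical inputs and settings give
#' identical results. Any stage may legitimately come up empty (e.g. no
#' module pair passes the Jaccard filter); the fit then completes with a
#' warning and zero counts rather than failing.
#'
#' @param expr_case,expr_control genes x samples expression matrices
#'   (normalized, log scale) for the two conditions.
#' @param edges interaction data frame (\code{gene_a}, \code{gene_b},
#'   \code{combined_score}).
#' @param score_threshold minimum combined score (inclusive), default 0.8.
#' @param edge_alpha per-edge correlation p-value cut (strict), default
#'   0.05.
#' @param clique_min,clique_max clique-size bounds, defaults 4 and 20.
#' @param merge_threshold minimum inter-connectivity to merge cliques,
#'   default 0.5.
#' @param interconnect inter-connectivity convention, \code{"geometric"}
#'   (default) or \code{"product"}.
#' @param jaccard_threshold minimum Jaccard similarity for a module pair,
#'   default 0.7.
#' @param min_module_size minimum module size on both sides of a pair,
#'   default 5.
#' @param attract_alpha FDR threshold for attractor calls, default 0.05.
#' @param tail sidedness of the module-level Welch test, \code{"two"}
#'   (default) or \code{"greater"}.
#' @param allow_many_to_many let a module join several pairs.
#' @return An object of class \code{"attracmod"}: a list with the
#'   destination \code{networks}, \code{cliques}, \code{modules} and module
#'   summaries per condition, the \code{pairs} table, per-gene
#'   \code{fstats}, the per-pair \code{results} table (Welch statistic,
#'   degrees of freedom, raw and BH-adjusted p-value, attractor flag), a
#'   stage-count \code{report}, and the \code{settings} used.
#' @examples
#' sim <- simulate_ppi_expression(n_genes = 80, n_planted_modules = 1,
#'                                rho_control = 0.8, seed = 3)
#' fit <- attracmod(sim$expr_case, sim$expr_control, sim$edges)
#' fit
#' summary(fit)
#' @export
attracmod <- function(expr_case, expr_control, edges,
                      score_threshold = 0.8, edge_alpha = 0.05,
                      clique_min = 4, clique_max = 20,
                      merge_threshold = 0.5,
                      interconnect = c("geometric", "product"),
                      jaccard_threshold = 0.7, min_module_size = 5,
                      attract_alpha = 0.05, tail = c("two", "greater"),
                      allow_many_to_many = FALSE) {
  interconnect <- match.arg(interconnect)
  tail <- match.arg(tail)
  cl <- match.call()

  profiled <- intersect(rownames(expr_case), rownames(expr_control))
  base <- build_base_network(edges, score_threshold, profiled)

  exprs <- list(case = expr_case, control = expr_control)
  networks <- cliques <- modules <- list()
  for (cond in c("case", "control")) {
    net <- reweight_network(base, exprs[[cond]], condition = cond)
    net <- significance_filter(net, edge_alpha)
    networks[[cond]] <- net
    cliques[[cond]] <- maximal_cliques(net, clique_min, clique_max)
    modules[[cond]] <- merge_cliques(cliques[[cond]], net,
                                     expr = exprs[[cond]],
                                     merge_threshold = merge_threshold,
                                     interconnect = interconnect,
                                     condition = cond)
  }

  pairs <- pair_modules(modules$case, modules$control,
                        jaccard_threshold = jaccard_threshold,
                        min_module_size = min_module_size,
                        allow_many_to_many = allow_many_to_many)

  fstats <- gene_f_statistics(expr_case[profiled, , drop = FALSE],
                              expr_control[profiled, , drop = FALSE])

  if (nrow(pairs) > 0L) {
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
      genes <- union(modules$case[[pairs$case_idx[r]]]$genes,
                     modules$control[[pairs$control_idx[r]]]$genes)
      attract_test(genes, fstats, tail = tail)
    })
    results <- cbind(pairs[, c("pair_id", "jaccard", "size_case",
                               "size_control")],
                     do.call(rbind, rows))
    results <- call_attractors(results, alpha = attract_alpha)
    rownames(results) <- NULL
  } else {
    warning("no module pair passed the Jaccard and size filters; ",
            "no attractor test performed")
    results <- data.frame(pair_id = character(0), jaccard = numeric(0),
                          size_case = integer(0), size_control = integer(0),
                          A = integer(0), V = integer(0),
                          mean_f_module = numeric(0),
                          mean_f_background = numeric(0),
                          s2_module = numeric(0), s2_background = numeric(0),
                          t_stat = numeric(0), df = numeric(0),
                          p_raw = numeric(0), p_adj = numeric(0),
                          is_attractor = logical(0),
                          stringsAsFactors = FALSE)
  }

  report <- list(
    schema_version = "1.0",
    nodes_base = length(base$nodes),
    edges_base = nrow(base$edges),
    edges_case = nrow(networks$case$edges),
    edges_control = nrow(networks$control$edges),
    cliques_case = length(cliques$case),
    cliques_control = length(cliques$control),
    modules_case = length(modules$case),
    modules_control = length(modules$control),
    pairs = nrow(pairs),
    attractors = sum(results$is_attractor))

  structure(list(call = cl, base_network = base, networks = networks,
                 cliques = cliques, modules = modules, pairs = pairs,
                 fstats = fstats, results = results, report = report,
                 settings = list(score_threshold = score_threshold,
                                 edge_alpha = edge_alpha,
                                 clique_min = clique_min,
                                 clique_max = clique_max,
                                 merge_threshold = merge_threshold,
                                 interconnect = interconnect,
                                 jaccard_threshold = jaccard_threshold,
                                 min_module_size = min_module_size,
                                 attract_alpha = attract_alpha,
                                 tail = tail,
                                 allow_many_to_many = allow_many_to_many)),
            class = "attracmod")
}

#' @export
print.attracmod <- function(x, ...) {
  r <- x$report
  cat("Attractor-module fit\n")
  cat(sprintf("  base network: %d nodes, %d edges (score >= %.2f)\n",
              r$nodes_base, r$edges_base, x$settings$score_threshold))
  cat(sprintf("  destination edges (p < %.2g): case %d, control %d\n",
              x$settings$edge_alpha, r$edges_case, r$edges_control))
  cat(sprintf("  cliques in [%d, %d]: case %d, control %d\n",
              x$settings$clique_min, x$settings$clique_max,
              r$cliques_case, r$cliques_control))
  cat(sprintf("  modules: case %d, control %d; pairs (J >= %.2f): %d\n",
              r$modules_case, r$modules_control,
              x$settings$jaccard_threshold, r$pairs))
  cat(sprintf("  attractor modules (BH-adjusted p < %.2g): %d\n",
              x$settings$attract_alpha, r$attractors))
  invisible(x)
}

#' @export
summary.attracmod <- function(object, ...) {
  structure(list(report = object$report, settings = object$settings,
                 results = object$results), class = "summary.attracmod")
}

#' @export
print.summary.attracmod <- function(x, ...) {
  cat("Stage counts:\n")
  counts <- unlist(x$report[-1L])
  print(counts)
  if (nrow(x$results)) {
    cat("\nModule pairs (Welch test of module vs background F):\n")
    out <- x$results[, c("pair_id", "jaccard", "size_case", "size_control",
                         "mean_f_module", "t_stat", "df", "p_raw", "p_adj",
                         "is_attractor")]
    print(out, digits = 4, row.names = FALSE)
  } else cat("\nNo module pairs.\n")
  invisible(x)
}

#' Plot per-pair F-statistic distributions
#'
#' Boxplots of the gene-level ANOVA F-statistics of every tested module
#' pair next to the background distribution, on a log scale. Attractor
#' pairs are shaded.
#'
#' @param x an \code{attracmod} fit with at least one tested pair.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.attracmod <- function(x, ...) {
  res <- x$results
  if (nrow(res) == 0L) {
    warning("no module pairs to plot")
    return(invisible(x))
  }
  f <- x$fstats$f_stat
  names(f) <- x$fstats$gene_id
  sets <- lapply(seq_len(nrow(res)), function(r) {
    genes <- union(
      x$modules$case[[res_idx(x, res$pair_id[r], "case_idx")]]$genes,
      x$modules$control[[res_idx(x, res$pair_id[r], "control_idx")]]$genes)
    f[intersect(names(f), genes)]
  })
  names(sets) <- res$pair_id
  allmod <- unique(unlist(lapply(sets, names)))
  sets <- c(list(background = f[setdiff(names(f), allmod)]), sets)
  cols <- c("grey85", ifelse(res$is_attractor, "indianred2", "white"))
  graphics::boxplot(lapply(sets, function(v) pmax(v, 1e-3)), log = "y",
                    col = cols, las = 2,
                    ylab = "gene F-statistic (log scale)", ...)
  graphics::abline(h = stats::qf(0.95, 1, attr(x$fstats, "S") - 2),
                   lty = 2, col = "grey40")
  invisible(x)
}

res_idx <- function(x, pid, col) x$pairs[x$pairs$pair_id == pid, col][1L]

#' Hypergeometric gene-set enrichment for a module
#'
#' One-sided hypergeometric (over-representation) test of a module's genes
#' against each supplied gene set, BH-adjusted across the sets. A light
#' stand-in for web-based ontology enrichment: gene sets come from the
#' caller, e.g. via [read_gmt()].
#'
#' @param module_genes gene ids of the module (must lie in
#'   \code{universe}).
#' @param gene_sets named list of gene-id vectors.
#' @param universe character vector of all testable gene ids.
#' @return Data frame sorted by p: \code{set_name}, \code{set_size},
#'   \code{overlap}, \code{p}, \code{p_adj}.
#' @export
hypergeom_enrich <- function(module_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("module genes must be contained in the universe")
  n <- length(module_genes)
  N <- length(universe)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(module_genes, set))
    data.frame(set_name = nm, set_size = length(set), overlap = k,
               p = stats::phyper(k - 1, length(set), N - length(set), n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$set_name), , drop = FALSE]
}
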