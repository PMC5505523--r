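#' Build the confidence-filtered base interaction network
#'
#' Keeps edges whose combined score passes the confidence threshold
#' (inclusive, default 0.8) and whose both endpoints are among the profiled
#' genes, i.e. genes present in the expression data. Self-loops and
#' duplicate edges are removed; the result is a simple undirected graph with
#' unassigned weights, ready for [reweight_network()].
#'
#' @param edges data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{combined_score} (scores in [0, 1]).
#' @param score_threshold minimum combined score retained (inclusive).
#' @param profiled_genes character vector of gene ids with expression data;
#'   edges touching other genes are dropped.
#' @return A \code{ppi_network} object: list with \code{edges} (data frame
#'   \code{gene_a}, \code{gene_b}, \code{score}, \code{weight},
#'   \code{p_value}), \code{nodes}, and \code{condition}.
#' @examples
#' e <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
#'                 combined_score = c(0.9, 0.8, 0.7))
#' build_base_network(e, 0.8, c("a", "b", "c"))$edges
#' @export
build_base_network <- function(edges, score_threshold = 0.8,
                               profiled_genes) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  s <- edges$combined_score
  if (any(s < 0 | s > 1)) stop("combined scores must lie in [0, 1]")
  keep <- s >= score_threshold &
    edges$gene_a %in% profiled_genes &
    edges$gene_b %in% profiled_genes &
    edges$gene_a != edges$gene_b
  e <- edges[keep, , drop = FALSE]
  # canonical unordered representation, first occurrence wins on duplicates
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  dup <- duplicated(paste(a, b, sep = "\r"))
  e <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                  score = e$combined_score[!dup],
                  weight = rep(NA_real_, sum(!dup)),
                  p_value = rep(NA_real_, sum(!dup)),
                  stringsAsFactors = FALSE)
  if (nrow(e) == 0L)
    warning("no edge passed the score threshold among profiled genes: ",
            "network is empty")
  new_ppi_network(e, condition = NA_character_)
}

new_ppi_network <- function(edges, condition = NA_character_) {
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 condition = condition),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network (%s): %d nodes, %d edges%s\n",
              ifelse(is.na(x$condition), "unlabelled", x$condition),
              length(x$nodes), nrow(x$edges),
              if (all(is.na(x$edges$weight))) ", weights unassigned" else ""))
  invisible(x)
}

#' Re-weight a network by expression correlation
#'
#' Assigns each edge the absolute Pearson correlation of its two genes'
#' expression profiles across the samples of one condition, plus a one-sided
#' p-value for positive association of the absolute correlation: with
#' \eqn{w = |r|} and \eqn{n} samples, \eqn{t = w\sqrt{n-2}/\sqrt{1-w^2}}
#' is referred to the Student t distribution with \eqn{n-2} degrees of
#' freedom and the upper tail taken. Genes with zero expression variance get
#' weight 0 and p-value 1 (reported via a message) so downstream graph code
#' never sees missing weights. Network nodes absent from the expression
#' matrix are dropped with a message.
#'
#' @param network a \code{ppi_network} (weights may be unassigned).
#' @param expr genes x samples matrix for one condition.
#' @param condition condition label stored on the result.
#' @return The re-weighted \code{ppi_network} with \code{weight} and
#'   \code{p_value} filled in.
#' @seealso [significance_filter()] for the destination-network cut.
#' @export
reweight_network <- function(network, expr, condition = NA_character_) {
  stopifnot(inherits(network, "ppi_network"))
  n <- ncol(expr)
  if (n <= 2L) stop("need more than 2 samples to test a correlation")
  missing_nodes <- setdiff(network$nodes, rownames(expr))
  e <- network$edges
  if (length(missing_nodes)) {
    message(length(missing_nodes),
            " network node(s) absent from the expression matrix; dropped")
    e <- e[!(e$gene_a %in% missing_nodes | e$gene_b %in% missing_nodes), ,
           drop = FALSE]
  }
  genes <- unique(c(e$gene_a, e$gene_b))
  x <- expr[genes, , drop = FALSE]
  ctr <- x - rowMeans(x)
  ss <- rowSums(ctr^2)
  zero_var <- ss == 0
  if (any(zero_var))
    message(sum(zero_var), " zero-variance gene(s): incident edges get ",
            "weight 0, p-value 1")
  scl <- ctr / sqrt(pmax(ss, .Machine$double.xmin))
  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  r <- rowSums(scl[ia, , drop = FALSE] * scl[ib, , drop = FALSE])
  r[zero_var[ia] | zero_var[ib]] <- 0
  w <- pmin(abs(r), 1)
  tt <- w * sqrt(n - 2) / sqrt(pmax(1 - w^2, 0))
  p <- stats::pt(tt, df = n - 2, lower.tail = FALSE)  # t = Inf -> p = 0
  p[zero_var[ia] | zero_var[ib]] <- 1
  e$weight <- w
  e$p_value <- p
  new_ppi_network(e, condition = condition)
}

#' Retain significant edges into the destination network
#'
#' Keeps edges whose correlation p-value is strictly below \code{alpha}
#' (default 0.05) and drops nodes left isolated. The result is the
#' per-condition "destination network" mined for cliques.
#'
#' @param network a re-weighted \code{ppi_network}.
#' @param alpha retention threshold on the per-edge p-value (strict).
#' @return The filtered \code{ppi_network}.
#' @export
significance_filter <- function(network, alpha = 0.05) {
  stopifnot(inherits(network, "ppi_network"))
  if (all(is.na(network$edges$p_value)) && nrow(network$edges) > 0L)
    stop("network has no edge p-values; run reweight_network() first")
  e <- network$edges[!is.na(network$edges$p_value) &
                       network$edges$p_value < alpha, , drop = FALSE]
  new_ppi_network(e, condition = network$condition)
}

# named lookup of edge weights, keys "a\rb" with a < b; absent pair -> 0
edge_weight_map <- function(network) {
  e <- network$edges
  w <- e$weight
  names(w) <- paste(e$gene_a, e$gene_b, sep = "\r")
  w
}

lookup_weight <- function(wmap, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- unname(wmap[key])
  w[is.na(w)] <- 0
  w
}
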