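#' Enumerate size-bounded maximal cliques
#'
#' Lists every maximal clique of the destination network whose size lies in
#' \code{[min_size, max_size]} (defaults 4 and 20). Enumeration uses the
#' pivoted Bron-Kerbosch algorithm (via \pkg{igraph}); cliques larger than
#' \code{max_size} are discarded, not truncated, and their sub-cliques are
#' not re-admitted since they are non-maximal. The returned order is
#' deterministic: decreasing size, then lexicographic on the sorted gene
#' ids.
#'
#' @param network a \code{ppi_network}.
#' @param min_size,max_size inclusive clique-size bounds.
#' @return List of character vectors (sorted gene ids), possibly empty.
#' @examples
#' e <- data.frame(gene_a = c("a", "a", "b", "a"),
#'                 gene_b = c("b", "c", "c", "d"),
#'                 combined_score = 1)
#' net <- build_base_network(e, 0.5, letters[1:4])
#' maximal_cliques(net, min_size = 3)
#' @export
maximal_cliques <- function(network, min_size = 4, max_size = 20) {
  stopifnot(inherits(network, "ppi_network"))
  if (nrow(network$edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = network$nodes)
  cl <- igraph::max_cliques(g, min = min_size, max = max_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  key <- vapply(cl, paste, "", collapse = "\r")
  cl[order(-lengths(cl), key)]
}

#' Weighted interaction density of a gene set
#'
#' The WID score of a clique \eqn{K} is
#' \deqn{score(K) = \sum_{a,b \in K, a \ne b} K(a,b) / (|K|(|K|-1)),}
#' the mean edge weight over all ordered pairs — each unordered edge counted
#' twice — so a clique whose edges all weigh \eqn{w} scores exactly \eqn{w}.
#' For merged modules the same formula is applied to the induced subgraph
#' with absent edges contributing weight 0.
#'
#' @param genes character vector of gene ids (at least 2).
#' @param network the re-weighted \code{ppi_network} supplying weights.
#' @return The WID, a number in [0, 1].
#' @export
wid <- function(genes, network) {
  .wid(genes, edge_weight_map(network))
}

.wid <- function(genes, wmap) {
  k <- length(genes)
  if (k < 2L) stop("WID needs at least 2 genes")
  idx <- utils::combn(k, 2L)
  w <- lookup_weight(wmap, genes[idx[1L, ]], genes[idx[2L, ]])
  sum(w) / (k * (k - 1) / 2)
}

#' Weighted inter-connectivity between two cliques
#'
#' The merge criterion between cliques \eqn{K_1}, \eqn{K_2}: with
#' \deqn{m_1 = \sum_{a \in K_1 - K_2} \sum_{b \in K_2} K(a,b) /
#'       (|K_1 - K_2| \cdot |K_2|)}
#' and \eqn{m_2} defined symmetrically, the inter-score is
#' \eqn{\sqrt{m_1 m_2}} (geometric mean, the default, which keeps the
#' statistic on the edge-weight scale) or the bare product
#' \eqn{m_1 m_2} (\code{mode = "product"}). Gene pairs without an edge
#' contribute weight 0. If either difference set is empty (one clique nested
#' in the other) the inter-score is 1.
#'
#' @param k1,k2 character vectors of gene ids.
#' @param network the re-weighted \code{ppi_network}.
#' @param mode \code{"geometric"} or \code{"product"}.
#' @return The inter-connectivity score.
#' @export
interconnectivity <- function(k1, k2, network,
                              mode = c("geometric", "product")) {
  .interconnectivity(k1, k2, edge_weight_map(network), match.arg(mode))
}

.interconnectivity <- function(k1, k2, wmap, mode) {
  d1 <- setdiff(k1, k2)
  d2 <- setdiff(k2, k1)
  if (length(d1) == 0L || length(d2) == 0L) return(1)
  cross <- function(from, to) {
    g <- expand.grid(a = from, b = to, stringsAsFactors = FALSE)
    sum(lookup_weight(wmap, g$a, g$b)) / (length(from) * length(to))
  }
  m1 <- cross(d1, k2)
  m2 <- cross(d2, k1)
  if (mode == "product") m1 * m2 else sqrt(m1 * m2)
}

#' Merge inter-connected cliques into modules
#'
#' Agglomerates cliques to a fixed point: whenever two current groups
#' contain cliques whose pairwise inter-connectivity reaches
#' \code{merge_threshold}, the groups are merged, until no pair qualifies.
#' That fixed point equals the connected components of the clique graph
#' linking cliques with inter-score \eqn{\ge} threshold, so the result does
#' not depend on processing order; cliques are nevertheless first sorted
#' deterministically (WID descending, then smallest gene id) so module
#' numbering is stable. Each module's gene set is the union of its member
#' cliques; its WID is recomputed on the union's induced subgraph (absent
#' edges weigh 0) and, when an expression matrix is supplied, its
#' correlation density \code{dcc} — the mean absolute pairwise correlation
#' over all gene pairs of the module — is attached.
#'
#' @param cliques list of gene-id vectors, e.g. from [maximal_cliques()].
#' @param network the re-weighted \code{ppi_network}.
#' @param expr optional genes x samples matrix for \code{dcc}.
#' @param merge_threshold minimum inter-connectivity to merge (inclusive).
#' @param interconnect \code{"geometric"} or \code{"product"}; see
#'   [interconnectivity()].
#' @param condition label attached to each module.
#' @return List of modules; each is a list with \code{genes} (sorted),
#'   \code{wid}, \code{dcc}, \code{source_cliques} (indices into the sorted
#'   clique list), \code{condition}. Ordered by WID descending, then
#'   smallest gene id.
#' @export
merge_cliques <- function(cliques, network, expr = NULL,
                          merge_threshold = 0.5,
                          interconnect = c("geometric", "product"),
                          condition = NA_character_) {
  interconnect <- match.arg(interconnect)
  if (length(cliques) == 0L) return(list())
  wmap <- edge_weight_map(network)
  scores <- vapply(cliques, .wid, 0, wmap = wmap)
  first <- vapply(cliques, min, "")
  ord <- order(-scores, first)
  cliques <- cliques[ord]
  scores <- scores[ord]

  nc <- length(cliques)
  comp <- seq_len(nc)            # union-find over cliques
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      if (find(i) == find(j)) next
      if (.interconnectivity(cliques[[i]], cliques[[j]], wmap,
                             interconnect) >= merge_threshold)
        comp[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(nc), find, 0L)
  groups <- split(seq_len(nc), root)

  modules <- lapply(groups, function(idx) {
    genes <- sort(unique(unlist(cliques[idx])))
    list(genes = genes,
         wid = .wid(genes, wmap),
         dcc = if (is.null(expr)) NA_real_ else module_dcc(genes, expr),
         source_cliques = unname(idx),
         condition = condition)
  })
  mwid <- vapply(modules, `[[`, 0, "wid")
  mfirst <- vapply(modules, function(m) m$genes[1L], "")
  unname(modules[order(-mwid, mfirst)])
}

#' Module correlation density
#'
#' Mean absolute pairwise Pearson correlation over all gene pairs of a
#' module, computed from the expression matrix of the module's condition.
#' Unlike WID it uses every pair, not only network edges, so it can exceed
#' the module's WID.
#'
#' @param genes gene ids (at least 2, all rows of \code{expr}).
#' @param expr genes x samples matrix.
#' @return The dcc in [0, 1].
#' @export
module_dcc <- function(genes, expr) {
  stopifnot(length(genes) >= 2L, all(genes %in% rownames(expr)))
  r <- suppressWarnings(stats::cor(t(expr[genes, , drop = FALSE])))
  r[is.na(r)] <- 0
  mean(abs(r[upper.tri(r)]))
}

#' Summarize a module list as a data frame
#'
#' @param modules list of modules from [merge_cliques()].
#' @return Data frame with one row per module: \code{module_id},
#'   \code{condition}, \code{size}, \code{wid}, \code{dcc}, \code{genes}
#'   (comma-joined).
#' @export
module_summary <- function(modules) {
  data.frame(
    module_id = seq_along(modules),
    condition = vapply(modules, `[[`, "", "condition"),
    size = vapply(modules, function(m) length(m$genes), 0L),
    wid = vapply(modules, `[[`, 0, "wid"),
    dcc = vapply(modules, `[[`, 0, "dcc"),
    genes = vapply(modules, function(m) paste(m$genes, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
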