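#' Jaccard similarity of two gene sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}.
#'
#' @param a,b character vectors of gene ids; not both empty.
#' @return A number in [0, 1]; 1 iff the sets are equal.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Pair case and control modules by gene composition
#'
#' Considers every cross-condition pair of modules with at least
#' \code{min_module_size} genes on both sides and Jaccard similarity at
#' least \code{jaccard_threshold}. By default each module joins at most one
#' pair: candidates are assigned greedily in order of decreasing Jaccard
#' (ties broken by the lexicographically smallest case-module gene id, then
#' control). \code{allow_many_to_many = TRUE} instead keeps every qualifying
#' pair. Retained pairs are labelled \code{"Module 1"}, \code{"Module 2"},
#' ... in decreasing Jaccard order.
#'
#' @param case_modules,control_modules module lists from [merge_cliques()].
#' @param jaccard_threshold minimum Jaccard similarity (inclusive).
#' @param min_module_size minimum gene count for both members.
#' @param allow_many_to_many keep all qualifying pairs instead of greedy
#'   one-to-one matching.
#' @return Data frame with one row per pair: \code{pair_id},
#'   \code{jaccard}, \code{case_idx}, \code{control_idx} (indices into the
#'   input lists), \code{size_case}, \code{size_control},
#'   \code{case_genes}, \code{control_genes} (comma-joined). Zero rows when
#'   nothing pairs.
#' @export
pair_modules <- function(case_modules, control_modules,
                         jaccard_threshold = 0.7, min_module_size = 5,
                         allow_many_to_many = FALSE) {
  empty <- data.frame(pair_id = character(0), jaccard = numeric(0),
                      case_idx = integer(0), control_idx = integer(0),
                      size_case = integer(0), size_control = integer(0),
                      case_genes = character(0),
                      control_genes = character(0),
                      stringsAsFactors = FALSE)
  ci <- which(vapply(case_modules, function(m) length(m$genes), 0L) >=
                min_module_size)
  ki <- which(vapply(control_modules, function(m) length(m$genes), 0L) >=
                min_module_size)
  if (length(ci) == 0L || length(ki) == 0L) return(empty)

  cand <- expand.grid(case_idx = ci, control_idx = ki)
  cand$jaccard <- mapply(function(i, j)
    jaccard(case_modules[[i]]$genes, control_modules[[j]]$genes),
    cand$case_idx, cand$control_idx)
  cand <- cand[cand$jaccard >= jaccard_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  key_c <- vapply(cand$case_idx,
                  function(i) case_modules[[i]]$genes[1L], "")
  key_k <- vapply(cand$control_idx,
                  function(j) control_modules[[j]]$genes[1L], "")
  cand <- cand[order(-cand$jaccard, key_c, key_k), , drop = FALSE]

  if (!allow_many_to_many) {
    used_c <- integer(0); used_k <- integer(0); keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (cand$case_idx[r] %in% used_c || cand$control_idx[r] %in% used_k)
        next
      keep[r] <- TRUE
      used_c <- c(used_c, cand$case_idx[r])
      used_k <- c(used_k, cand$control_idx[r])
    }
    cand <- cand[keep, , drop = FALSE]
  }
  data.frame(
    pair_id = paste("Module", seq_len(nrow(cand))),
    jaccard = cand$jaccard,
    case_idx = cand$case_idx,
    control_idx = cand$control_idx,
    size_case = vapply(cand$case_idx,
                       function(i) length(case_modules[[i]]$genes), 0L),
    size_control = vapply(cand$control_idx,
                          function(j) length(control_modules[[j]]$genes),
                          0L),
    case_genes = vapply(cand$case_idx, function(i)
      paste(case_modules[[i]]$genes, collapse = ","), ""),
    control_genes = vapply(cand$control_idx, function(j)
      paste(control_modules[[j]]$genes, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}
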