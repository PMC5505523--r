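#' Read and write gene expression matrices
#'
#' Expression files are tab-separated with a header row of sample ids and a
#' first column of gene ids. Values are normalized log-scale intensities.
#'
#' @param path file path.
#' @return \code{read_expression} returns a numeric matrix with gene-id row
#'   names and sample-id column names.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1L]])) stop("duplicate gene ids in ", path)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing expression values in ", path)
  m
}

#' @rdname read_expression
#' @param expr genes x samples numeric matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write scored interaction edge lists
#'
#' Edge files are three-column tab-separated tables (\code{gene_a},
#' \code{gene_b}, \code{combined_score}), mirroring a STRING detailed-links
#' extract after identifier mapping. Scores are confidences in [0, 1].
#'
#' @param path file path.
#' @return \code{read_edges} returns a data frame with columns
#'   \code{gene_a}, \code{gene_b}, \code{combined_score}.
#' @export
read_edges <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("gene_a", "gene_b", "combined_score")
  d$combined_score <- as.numeric(d$combined_score)
  d
}

#' @rdname read_edges
#' @param edges data frame of edges.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}
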