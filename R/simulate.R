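#' Simulate expression matrices and a PPI edge list with planted modules
#'
#' Generates a two-condition gene expression data set plus a STRING-style
#' scored interaction list in which a known set of gene modules is planted,
#' so that the whole module-discovery pipeline can be validated against a
#' ground truth. Each planted module is a complete subgraph in the edge list
#' (every internal edge carries \code{planted_edge_score}) and its genes are
#' equicorrelated within each condition: gene \eqn{i} of module \eqn{m} is
#' drawn as \eqn{\sqrt{\rho}\, z_m + \sqrt{1-\rho}\, \epsilon_i} with one
#' shared factor \eqn{z_m} per sample, which gives pairwise correlation
#' exactly \eqn{\rho} in expectation. Background genes are independent
#' Gaussian noise; background edges are i.i.d. Bernoulli with scores drawn
#' uniformly on \code{score_range}.
#'
#' A module is ground-truth "attractor" when it carries any differential
#' signal: a case-condition mean shift (\code{mean_shift != 0}) or a
#' correlation contrast (\code{rho_case != rho_control}). Setting
#' \code{mean_shift = 0} and \code{rho_case == rho_control} yields an
#' all-null data set (all attractor flags \code{FALSE}) for calibration
#' studies.
#'
#' Each module draws from its own sub-seed (\code{seed + m}), background
#' expression and the edge list from fixed offsets of \code{seed}, so the
#' draw order is stable: enlarging the background does not perturb the
#' planted modules. The caller's RNG state is restored on exit.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_condition samples per condition (balanced design).
#' @param n_planted_modules number of planted modules.
#' @param planted_module_size genes per planted module; must lie in [5, 20]
#'   so planted modules survive the pipeline's clique- and module-size
#'   filters.
#' @param rho_case,rho_control target within-module pairwise correlation in
#'   each condition, in [0, 1).
#' @param mean_shift expression shift (in units of \code{noise_sd}) added to
#'   attractor-module genes in the case condition.
#' @param background_edge_prob probability of a background edge between any
#'   pair of genes not inside one planted module.
#' @param planted_edge_score combined score assigned to planted intra-module
#'   edges, in [0, 1].
#' @param score_range range of the uniform distribution for background edge
#'   scores.
#' @param noise_sd marginal standard deviation of expression values.
#' @param seed integer seed; fully determines all outputs.
#'
#' @return An object of class \code{"attracmod_sim"}: a list with elements
#'   \code{expr_case} and \code{expr_control} (genes x samples matrices),
#'   \code{edges} (data frame \code{gene_a}, \code{gene_b},
#'   \code{combined_score}), \code{sample_sheet} (data frame
#'   \code{sample_id}, \code{condition}), \code{ground_truth} (list with
#'   \code{planted_modules}, a list of gene-id vectors, and
#'   \code{attractor_flags}), and \code{config}.
#'
#' @seealso [write_sim()] to serialize all parts as plain-text files,
#'   [attracmod()] to run the pipeline on the result.
#' @examples
#' sim <- simulate_ppi_expression(n_genes = 60, n_planted_modules = 1,
#'                                background_edge_prob = 0.02, seed = 7)
#' sim$ground_truth$planted_modules
#' @export
simulate_ppi_expression <- function(n_genes = 400,
                                    n_samples_per_condition = 18,
                                    n_planted_modules = 2,
                                    planted_module_size = 6,
                                    rho_case = 0.9,
                                    rho_control = 0.3,
                                    mean_shift = 1,
                                    background_edge_prob = 0.01,
                                    planted_edge_score = 0.95,
                                    score_range = c(0.4, 1),
                                    noise_sd = 1,
                                    seed = 1L) {
  if (planted_module_size < 5 || planted_module_size > 20)
    stop("planted_module_size must lie in [5, 20]")
  if (n_planted_modules * planted_module_size > n_genes)
    stop("planted modules need ", n_planted_modules * planted_module_size,
         " genes but n_genes = ", n_genes)
  for (rho in c(rho_case, rho_control))
    if (rho < 0 || rho >= 1) stop("correlations must lie in [0, 1)")
  if (background_edge_prob <= 0 || background_edge_prob >= 1)
    stop("background_edge_prob must lie in (0, 1)")
  if (planted_edge_score < 0 || planted_edge_score > 1)
    stop("planted_edge_score must lie in [0, 1]")
  seed <- as.integer(seed)

  # restore the caller's RNG stream afterwards
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))

  n  <- n_samples_per_condition
  M  <- n_planted_modules
  k  <- planted_module_size
  gene_ids <- sprintf("g%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
  case_ids <- sprintf("case_%02d", seq_len(n))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(n))

  expr_case <- matrix(NA_real_, n_genes, n,
                      dimnames = list(gene_ids, case_ids))
  expr_ctrl <- matrix(NA_real_, n_genes, n,
                      dimnames = list(gene_ids, ctrl_ids))

  differential <- (mean_shift != 0) || (rho_case != rho_control)
  planted <- vector("list", M)
  flags <- rep(differential, length.out = max(M, 0L))

  equicorr <- function(rho, n_genes_m, n_samp) {
    z <- stats::rnorm(n_samp)
    eps <- matrix(stats::rnorm(n_genes_m * n_samp), n_genes_m, n_samp)
    sqrt(rho) * matrix(z, n_genes_m, n_samp, byrow = TRUE) +
      sqrt(1 - rho) * eps
  }

  for (m in seq_len(M)) {
    rows <- ((m - 1L) * k + 1L):(m * k)
    planted[[m]] <- gene_ids[rows]
    set.seed(seed + m)
    xc <- equicorr(rho_case, k, n)
    xk <- equicorr(rho_control, k, n)
    if (flags[m] && mean_shift != 0) xc <- xc + mean_shift
    expr_case[rows, ] <- noise_sd * xc
    expr_ctrl[rows, ] <- noise_sd * xk
  }

  bg_rows <- setdiff(seq_len(n_genes), seq_len(M * k))
  if (length(bg_rows)) {
    set.seed(seed + 1000001L)
    expr_case[bg_rows, ] <-
      noise_sd * matrix(stats::rnorm(length(bg_rows) * n), length(bg_rows), n)
    expr_ctrl[bg_rows, ] <-
      noise_sd * matrix(stats::rnorm(length(bg_rows) * n), length(bg_rows), n)
  }

  # edge list: planted cliques first, then i.i.d. background pairs
  set.seed(seed + 2000002L)
  pl_a <- character(0); pl_b <- character(0)
  for (m in seq_len(M)) {
    g <- planted[[m]]
    idx <- utils::combn(length(g), 2L)
    pl_a <- c(pl_a, g[idx[1L, ]])
    pl_b <- c(pl_b, g[idx[2L, ]])
  }
  intra <- paste(pl_a, pl_b)

  all_idx <- utils::combn(n_genes, 2L)
  a <- gene_ids[all_idx[1L, ]]
  b <- gene_ids[all_idx[2L, ]]
  keep <- stats::runif(length(a)) < background_edge_prob
  score <- stats::runif(length(a), score_range[1L], score_range[2L])
  keep[paste(a, b) %in% intra] <- FALSE

  edges <- data.frame(
    gene_a = c(pl_a, a[keep]),
    gene_b = c(pl_b, b[keep]),
    combined_score = c(rep(planted_edge_score, length(pl_a)), score[keep]),
    stringsAsFactors = FALSE)

  structure(list(
    expr_case = expr_case,
    expr_control = expr_ctrl,
    edges = edges,
    sample_sheet = data.frame(
      sample_id = c(case_ids, ctrl_ids),
      condition = rep(c("case", "control"), each = n),
      stringsAsFactors = FALSE),
    ground_truth = list(planted_modules = planted,
                        attractor_flags = flags),
    config = list(n_genes = n_genes, n_samples_per_condition = n,
                  n_planted_modules = M, planted_module_size = k,
                  rho_case = rho_case, rho_control = rho_control,
                  mean_shift = mean_shift,
                  background_edge_prob = background_edge_prob,
                  planted_edge_score = planted_edge_score,
                  score_range = score_range, noise_sd = noise_sd,
                  seed = seed)),
    class = "attracmod_sim")
}

#' @export
print.attracmod_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic PPI/expression data set\n")
  cat(sprintf("  %d genes x %d+%d samples; %d planted module(s) of size %d\n",
              cfg$n_genes, cfg$n_samples_per_condition,
              cfg$n_samples_per_condition, cfg$n_planted_modules,
              cfg$planted_module_size))
  cat(sprintf("  rho case/control = %.2f/%.2f, mean shift = %.2f sd\n",
              cfg$rho_case, cfg$rho_control, cfg$mean_shift))
  cat(sprintf("  %d interactions (%d planted), seed %d\n",
              nrow(x$edges),
              sum(x$edges$combined_score == cfg$planted_edge_score),
              cfg$seed))
  invisible(x)
}

#' Write a simulated data set as plain-text files
#'
#' Serializes an [simulate_ppi_expression()] result into the file formats the
#' pipeline reads: two expression TSVs, a two-column sample sheet, a
#' three-column scored edge list, and the ground truth as JSON.
#'
#' @param sim an \code{attracmod_sim} object.
#' @param dir output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written
#'   (\code{expr_case}, \code{expr_control}, \code{sample_sheet},
#'   \code{edges}, \code{ground_truth}).
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "attracmod_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expr_case = file.path(dir, "expression_case.tsv"),
    expr_control = file.path(dir, "expression_control.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    edges = file.path(dir, "edges.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_expression(sim$expr_case, paths[["expr_case"]])
  write_expression(sim$expr_control, paths[["expr_control"]])
  utils::write.table(sim$sample_sheet, paths[["sample_sheet"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edges(sim$edges, paths[["edges"]])
  jsonlite::write_json(sim$ground_truth, paths[["ground_truth"]],
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(paths)
}
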