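#' Per-gene one-way ANOVA F-statistics across two conditions
#'
#' Fits, for each gene, the one-factor model \eqn{y_{rg} = O + O_g +
#' \epsilon_{rg}} over the \eqn{G = 2} condition groups and returns the
#' F-statistic testing equal group effects. With \eqn{p_g} samples in group
#' \eqn{g}, \eqn{S} samples in total, group means \eqn{\bar y_{\cdot g}}
#' and overall mean \eqn{\bar y_{\cdot\cdot}} taken as the unweighted mean
#' of the group means (identical to the pooled mean for balanced designs):
#' \deqn{MSS = \frac{1}{G-1} \sum_g p_g (\bar y_{\cdot g} -
#'       \bar y_{\cdot\cdot})^2, \quad
#'       RSS = \frac{1}{S-G} \sum_g \sum_r (y_{rg} - \bar y_{\cdot g})^2,
#'       \quad F = MSS / RSS.}
#' For two balanced groups F equals the square of the pooled-variance
#' two-sample t-statistic. Genes with zero residual variance but a group
#' difference get \code{F = Inf} (with a warning); genes constant
#' everywhere get \code{F = 0}.
#'
#' @param expr_case,expr_control genes x samples matrices over the same
#'   gene universe, at least 2 samples each.
#' @return Data frame with one row per gene: \code{gene_id},
#'   \code{mean_case}, \code{mean_control}, \code{grand_mean}, \code{mss},
#'   \code{rss}, \code{f_stat}; attributes \code{G}, \code{S}, \code{p_g}.
#' @export
gene_f_statistics <- function(expr_case, expr_control) {
  if (!setequal(rownames(expr_case), rownames(expr_control)))
    stop("case and control matrices must cover the same genes")
  expr_control <- expr_control[rownames(expr_case), , drop = FALSE]
  p1 <- ncol(expr_case); p2 <- ncol(expr_control)
  if (p1 < 2L || p2 < 2L) stop("need at least 2 samples per condition")
  G <- 2L; S <- p1 + p2
  m1 <- rowMeans(expr_case)
  m2 <- rowMeans(expr_control)
  gm <- (m1 + m2) / G
  mss <- (p1 * (m1 - gm)^2 + p2 * (m2 - gm)^2) / (G - 1)
  rss <- (rowSums((expr_case - m1)^2) + rowSums((expr_control - m2)^2)) /
    (S - G)
  f <- ifelse(rss > 0, mss / rss, ifelse(mss > 0, Inf, 0))
  if (any(is.infinite(f)))
    warning(sum(is.infinite(f)),
            " gene(s) with zero residual variance: F reported as Inf")
  structure(data.frame(gene_id = rownames(expr_case),
                       mean_case = m1, mean_control = m2, grand_mean = gm,
                       mss = mss, rss = rss, f_stat = f,
                       row.names = NULL, stringsAsFactors = FALSE),
            G = G, S = S, p_g = c(p1, p2))
}

#' Welch test of a module's F-statistics against the background
#'
#' The module-level GSEA-ANOVA statistic: with \eqn{A} module genes of mean
#' F-statistic \eqn{\bar F_A} and sample variance \eqn{S_A^2}, and \eqn{V}
#' background genes (every gene with a finite F outside the module) with
#' \eqn{\bar F_V}, \eqn{S_V^2},
#' \deqn{T_M = \frac{\bar F_A - \bar F_V}
#'       {\sqrt{S_A^2/A + S_V^2/V}},}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{w = \frac{(S_A^2/A + S_V^2/V)^2}
#'       {\frac{S_A^4}{A^2 (A-1)} + \frac{S_V^4}{V^2 (V-1)}}.}
#' The p-value is two-sided by default (\code{tail = "two"});
#' \code{tail = "greater"} tests for module F-statistics exceeding the
#' background.
#'
#' @param module_genes gene ids of the module under test.
#' @param fstats result of [gene_f_statistics()].
#' @param tail \code{"two"} or \code{"greater"}.
#' @return One-row data frame: \code{A}, \code{V}, \code{mean_f_module},
#'   \code{mean_f_background}, \code{s2_module}, \code{s2_background},
#'   \code{t_stat}, \code{df}, \code{p_raw}.
#' @export
attract_test <- function(module_genes, fstats, tail = c("two", "greater")) {
  tail <- match.arg(tail)
  ok <- is.finite(fstats$f_stat)
  inmod <- fstats$gene_id %in% module_genes
  fa <- fstats$f_stat[ok & inmod]
  fv <- fstats$f_stat[ok & !inmod]
  A <- length(fa); V <- length(fv)
  if (A < 2L) stop("need at least 2 module genes with a finite F-statistic")
  if (V < 2L) stop("need at least 2 background genes with a finite F-statistic")
  sa2 <- stats::var(fa); sv2 <- stats::var(fv)
  if (sa2 == 0 && sv2 == 0)
    stop("zero F-statistic variance in both module and background")
  se2 <- sa2 / A + sv2 / V
  t_stat <- (mean(fa) - mean(fv)) / sqrt(se2)
  w <- se2^2 / (sa2^2 / (A^2 * (A - 1)) + sv2^2 / (V^2 * (V - 1)))
  p <- if (tail == "two") 2 * stats::pt(abs(t_stat), df = w,
                                        lower.tail = FALSE)
       else stats::pt(t_stat, df = w, lower.tail = FALSE)
  data.frame(A = A, V = V,
             mean_f_module = mean(fa), mean_f_background = mean(fv),
             s2_module = sa2, s2_background = sv2,
             t_stat = t_stat, df = w, p_raw = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values for multiple testing by the Benjamini-Hochberg step-up
#' procedure controlling the false discovery rate: the i-th smallest p
#' becomes \eqn{\min_{j \ge i} p_{(j)} n / j}, clipped at 1, returned in
#' the input order. In the module pipeline the adjustment runs across the
#' module pairs under test, not across genes.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag attractor modules at an FDR threshold
#'
#' Adds BH-adjusted p-values to a table of per-pair Welch results and flags
#' as attractor modules the pairs with \code{p_adj < alpha}. Rows are
#' returned sorted by adjusted then raw p-value.
#'
#' @param results data frame with columns \code{pair_id} and \code{p_raw}
#'   (one row per module pair), e.g. assembled from [attract_test()].
#' @param alpha FDR threshold (strict), default 0.05.
#' @return The input with columns \code{p_adj} and \code{is_attractor}
#'   appended, sorted by \code{p_adj}.
#' @export
call_attractors <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), "p_raw" %in% names(results))
  results$p_adj <- bh_adjust(results$p_raw)
  results$is_attractor <- results$p_adj < alpha
  results[order(results$p_adj, results$p_raw, results$pair_id), ,
          drop = FALSE]
}
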