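#' Mann-Whitney U comparison with rank-biserial effect size
#'
#' Two-sided comparison of two independent groups. `U` counts pairs where a
#' group-A value exceeds a group-B value (ties count 1/2, via midranks);
#' the rank-biserial effect size is `r = 1 - 2U/(n1*n2)`, so `|r| = 1`
#' exactly at complete separation and `r = 0` when the groups coincide as
#' multisets. The p-value is exact (network enumeration) when
#' `min(n1, n2) <= 8` and there are no ties, otherwise a normal
#' approximation with tie and continuity correction.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return A `stat_test_result`: `statistic` (U for group A), `p_value`,
#'   `effect_r`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(group_a); n2 <- length(group_b)
  ranks <- rank(c(group_a, group_b))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2     # pairs a > b (midranks)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- min(n1, n2) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  stat_test_result(statistic = u, p_value = wt$p.value,
                   effect_r = 1 - 2 * u / (n1 * n2), n1 = n1, n2 = n2,
                   method = if (exact) "Mann-Whitney U (exact)"
                            else "Mann-Whitney U (normal approximation)")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences are taken as `x - y`; zero differences are dropped (count
#' reported). The standardized statistic is
#' `Z = (W+ - m(m+1)/4) / sigma_W` with the tie-corrected null SD and `m`
#' the number of non-zero differences, so `Z > 0` means `x` tends to exceed
#' `y`. The p-value is exact (enumeration) for `m <= 12` without tied
#' absolute differences, otherwise a normal approximation with continuity
#' correction. All differences zero yields a degenerate result flagged with
#' `p = 1`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return A `stat_test_result` with `statistic` = Z (and attributes
#'   `w_plus`, `n_zero`, `degenerate`).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("'x' and 'y' must be paired vectors of equal length >= 1",
         call. = FALSE)
  d_all <- x - y
  nz <- sum(d_all == 0)
  keep <- d_all != 0
  d <- d_all[keep]
  m <- length(d)
  if (m == 0L) {
    out <- stat_test_result(statistic = 0, p_value = 1, effect_r = 0,
                            n1 = length(x), n2 = length(x),
                            method = "Wilcoxon signed rank (degenerate: all differences zero)")
    out$degenerate <- TRUE
    return(out)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  tie_tab <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  ties <- anyDuplicated(abs(d)) > 0
  exact <- m <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x[keep], y[keep], paired = TRUE, exact = exact,
                       correct = TRUE))
  out <- stat_test_result(statistic = z, p_value = wt$p.value,
                          effect_r = max(-1, min(1, (w_plus - mu) / (m * (m + 1) / 4))),
                          n1 = length(x), n2 = length(x),
                          method = if (exact) "Wilcoxon signed rank (exact)"
                                   else "Wilcoxon signed rank (normal approximation)")
  out$w_plus <- w_plus; out$n_zero <- nz; out$degenerate <- FALSE
  out
}

#' Spearman rank correlation
#'
#' `rho` is Pearson correlation of midranks; the p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (the documented approximation, valid with ties).
#' Constant input is flagged as undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A `stat_test_result` with `statistic` = rho (also in `effect_r`).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_test_result(statistic = rho, p_value = p, effect_r = rho,
                   n1 = n, n2 = n, method = "Spearman rank correlation (t approximation)")
}

stat_test_result <- function(statistic, p_value, effect_r, n1, n2, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_r = effect_r, n1 = n1, n2 = n2, method = method),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> %s\n  statistic = %.4g, p = %.4g, effect r = %.3f (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$effect_r, x$n1, x$n2))
  invisible(x)
}
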