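#' A-priori power design for the two-sample t test
#'
#' `power_spec()` records the design: the standardized effect (Cohen's d),
#' the two-tailed significance level, the target power and the allocation
#' ratio `n2 / n1`. `sample_size_two_group_t()` returns the smallest integer
#' per-group size whose exact power - computed from the noncentral t
#' distribution with `df = n1 + n2 - 2` and noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` - reaches the target. The result is never
#' below the closed-form normal-approximation bound
#' `(z_{1-alpha/2} + z_{power})^2 * 2 / d^2` (for 1:1 allocation).
#'
#' @param effect_d Cohen's d, > 0.
#' @param alpha two-tailed significance level in (0, 1).
#' @param target_power desired power in (0, 1).
#' @param allocation ratio `n2 / n1` (default 1).
#' @return `power_spec()`: an object of class `power_spec`.
#' @export
power_spec <- function(effect_d = 0.90, alpha = 0.05, target_power = 0.80,
                       allocation = 1) {
  if (effect_d <= 0) stop("'effect_d' must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || target_power <= 0 || target_power >= 1)
    stop("'alpha' and 'target_power' must lie in (0, 1)", call. = FALSE)
  if (target_power <= alpha)
    stop("target power must exceed alpha", call. = FALSE)
  if (allocation <= 0) stop("'allocation' must be > 0", call. = FALSE)
  structure(list(effect_d = effect_d, alpha = alpha,
                 target_power = target_power, allocation = allocation),
            class = "power_spec")
}

# Exact power of the two-sided two-sample t test.
t_test_power <- function(n1, n2, d, alpha) {
  df <- n1 + n2 - 2
  if (df < 1) return(0)
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}

#' @rdname power_spec
#' @param spec a [power_spec].
#' @return `sample_size_two_group_t()`: list with `n_per_group` (n1),
#'   `n_group2`, `n_total` and `achieved_power`.
#' @export
sample_size_two_group_t <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  n1 <- 2L
  repeat {
    n2 <- max(2L, as.integer(ceiling(spec$allocation * n1)))
    pw <- t_test_power(n1, n2, spec$effect_d, spec$alpha)
    if (pw >= spec$target_power) break
    n1 <- n1 + 1L
    if (n1 > 1e6) stop("sample-size search did not terminate", call. = FALSE)
  }
  list(n_per_group = n1, n_group2 = n2, n_total = n1 + n2,
       achieved_power = pw)
}

#' Monte-Carlo power of the two-sample t test
#'
#' Simulates `reps` replicates of two normal samples (common SD 1, mean
#' difference `effect_d`) of `n_per_group` each and returns the fraction in
#' which the two-sided two-sample t test rejects at `alpha`. The t
#' statistics are computed vectorized (pooled-variance form, identical to
#' [stats::t.test()] with `var.equal = TRUE`).
#'
#' @param effect_d true standardized mean difference.
#' @param n_per_group per-group sample size.
#' @param alpha two-tailed significance level.
#' @param reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer RNG seed.
#' @return Rejection proportion.
#' @export
empirical_power <- function(effect_d, n_per_group, alpha = 0.05,
                            reps = 10000L, seed = 1L) {
  if (reps < 100) stop("'reps' must be >= 100", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- n_per_group
  x <- matrix(stats::rnorm(reps * n, mean = effect_d), reps, n)
  y <- matrix(stats::rnorm(reps * n), reps, n)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (n - 1)
  sp2 <- ((n - 1) * vx + (n - 1) * vy) / (2 * n - 2)
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  crit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  mean(abs(tstat) > crit)
}
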