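# Independent oracles used across the suite: naive per-pixel loops and
# exhaustive enumerations, deliberately written without reusing package
# internals.

# Naive double-loop depth map (natural log).
loop_depth_map <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    a <- max(m[i, ])
    if (a == 0) next
    for (j in seq_len(ncol(m))) {
      b <- m[i, j]
      out[i, j] <- (log((a - b)^2 + 1) * sin(pi / 2 * b / a))^2
    }
  }
  out
}

# Brute-force 'same' correlation with reflect padding (no edge repeat).
loop_conv2_reflect <- function(m, kern) {
  k <- (nrow(kern) - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {            # reflect 1-based index into [1, n]
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -k:k) for (dj in -k:k)
      acc <- acc + kern[di + k + 1, dj + k + 1] *
        m[refl(i + di, nr), refl(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# Exhaustive Mann-Whitney two-sided p: all label assignments of the pooled
# sample, U = #(a > b) pairs with ties counted 1/2.
enum_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(av, bv)
    sum(outer(av, bv, ">") + 0.5 * outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Exhaustive Wilcoxon signed-rank two-sided p over all 2^m sign flips.
enum_signed_rank <- function(x, y) {
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mu <- m * (m + 1) / 4
  p <- if (w_obs >= mu) 2 * mean(ws >= w_obs) else 2 * mean(ws <= w_obs)
  list(w = w_obs, p = min(1, p))
}

# AUC by exhaustive pair counting (ties 1/2), higher scores positive.
enum_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Scalar bilinear interpolation at 0-based (y, x) with border clamping.
scalar_bilinear <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y <- min(max(y, 0), nr - 1); x <- min(max(x, 0), nc - 1)
  y0 <- min(floor(y), nr - 2); y0 <- max(y0, 0)
  x0 <- min(floor(x), nc - 2); x0 <- max(x0, 0)
  if (nr == 1) y0 <- 0
  if (nc == 1) x0 <- 0
  ty <- y - y0; tx <- x - x0
  y1 <- min(y0 + 1, nr - 1); x1 <- min(x0 + 1, nc - 1)
  (1 - ty) * ((1 - tx) * m[y0 + 1, x0 + 1] + tx * m[y0 + 1, x1 + 1]) +
    ty * ((1 - tx) * m[y1 + 1, x0 + 1] + tx * m[y1 + 1, x1 + 1])
}

# Random 8-bit test matrix.
rand_roi <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}
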