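# Independent oracles used to check the package's statistics and fits.

# Permutation p-value for the two-sided Welch comparison: relabel group
# membership B times and compare |t*| against the observed |t|.
perm_welch_p <- function(a, b, B = 1e5, seed = 1) {
  set.seed(seed)
  pool <- c(a, b); n <- length(pool); n1 <- length(a); n2 <- length(b)
  t_obs <- abs(welch_t_test(a, b)$t)
  idx <- vapply(seq_len(B), function(i) sample.int(n, n1), integer(n1))
  X <- matrix(pool[idx], n1, B)
  s1 <- colSums(X); q1 <- colSums(X^2)
  s2 <- sum(pool) - s1; q2 <- sum(pool^2) - q1
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  t_star <- abs((m1 - m2) / sqrt(v1 / n1 + v2 / n2))
  (1 + sum(t_star >= t_obs)) / (B + 1)
}

# Permutation p-value for the unequal-covariance two-sample T2 (2D case),
# vectorized over permutations via group sufficient statistics.
perm_hotelling_p <- function(a, b, B = 1e5, seed = 1) {
  stopifnot(ncol(a) == 2, ncol(b) == 2)
  set.seed(seed)
  pool <- rbind(a, b); n <- nrow(pool); n1 <- nrow(a); n2 <- nrow(b)
  T2_obs <- hotelling_unequal(a, b)$T2
  x <- pool[, 1]; y <- pool[, 2]
  tot <- c(sum(x), sum(y), sum(x^2), sum(y^2), sum(x * y))
  idx <- vapply(seq_len(B), function(i) sample.int(n, n1), integer(n1))
  Xs <- matrix(x[idx], n1, B); Ys <- matrix(y[idx], n1, B)
  sx1 <- colSums(Xs); sy1 <- colSums(Ys)
  qx1 <- colSums(Xs^2); qy1 <- colSums(Ys^2); qxy1 <- colSums(Xs * Ys)
  stat_of <- function(sx, sy, qx, qy, qxy, m) {
    mx <- sx / m; my <- sy / m
    vxx <- (qx - m * mx^2) / (m - 1)
    vyy <- (qy - m * my^2) / (m - 1)
    vxy <- (qxy - m * mx * my) / (m - 1)
    list(mx = mx, my = my, sxx = vxx / m, syy = vyy / m, sxy = vxy / m)
  }
  g1 <- stat_of(sx1, sy1, qx1, qy1, qxy1, n1)
  g2 <- stat_of(tot[1] - sx1, tot[2] - sy1, tot[3] - qx1, tot[4] - qy1, tot[5] - qxy1, n2)
  dx <- g1$mx - g2$mx; dy <- g1$my - g2$my
  Sxx <- g1$sxx + g2$sxx; Syy <- g1$syy + g2$syy; Sxy <- g1$sxy + g2$sxy
  det_ <- Sxx * Syy - Sxy^2
  T2_star <- (dx^2 * Syy - 2 * dx * dy * Sxy + dy^2 * Sxx) / det_
  (1 + sum(T2_star >= T2_obs)) / (B + 1)
}

# Brute-force optimal 1D two-cluster partition (minimum within-cluster SS
# over every threshold), returning the high-cluster membership.
brute_two_cluster <- function(x) {
  xs <- sort(unique(x))
  best <- NULL; best_wss <- Inf
  for (thr in xs[-length(xs)]) {
    hi <- x > thr
    wss <- sum((x[!hi] - mean(x[!hi]))^2) + sum((x[hi] - mean(x[hi]))^2)
    if (wss < best_wss) { best_wss <- wss; best <- hi }
  }
  best
}
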