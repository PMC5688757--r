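## Two-group statistics used for the ablation-vs-control strain comparison.

#' Welch's unequal-variance t test
#'
#' Thin wrapper around [stats::t.test()] (two-sided, `var.equal = FALSE`)
#' returning a tidy one-row tibble with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param a,b numeric vectors, each of length >= 2; at least one group must
#'   have positive variance.
#' @return Tibble with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 values.")
  if (stats::var(a) <= 0 && stats::var(b) <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(tibble(t = 0, df = NA_real_, p_value = 1))
    abort("Both groups have zero variance with different means; the t statistic is undefined.")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter), p_value = ht$p.value)
}

#' Hotelling T-squared test with unequal covariances
#'
#' Two-sample multivariate comparison that does not pool the group
#' covariances: `T2 = d' S^-1 d` with `d` the mean difference and
#' `S = S1/n1 + S2/n2`. The null distribution is approximated by a
#' moment-matched F (Yao-type degrees of freedom), appropriate when the two
#' groups may have different covariance structures.
#'
#' @param a,b numeric matrices (rows = observations, cols = variables), both
#'   with the same number of columns `p`; each group needs more than `p + 1`
#'   observations.
#' @return Tibble with `T2`, `df1`, `df2` (the F reference has `df1 = p`,
#'   `df2 = f - p + 1`), `p_value`.
#' @export
hotelling_unequal <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  p <- ncol(a)
  if (ncol(b) != p) abort("Groups must have the same number of variables.")
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 <= p + 1 || n2 <= p + 1) abort("Each group needs more than p + 1 observations.")
  d <- colMeans(a) - colMeans(b)
  S1 <- stats::cov(a) / n1
  S2 <- stats::cov(b) / n2
  S <- S1 + S2
  if (rcond_sym(S) < 1e-12) abort("Combined covariance is (nearly) singular.")
  Sinv_d <- solve(S, d)
  T2 <- sum(d * Sinv_d)
  if (T2 <= 0) return(tibble(T2 = 0, df1 = p, df2 = NA_real_, p_value = 1))
  # Yao (1965) moment-matched degrees of freedom
  w1 <- sum(Sinv_d * (S1 %*% Sinv_d)) / T2
  w2 <- sum(Sinv_d * (S2 %*% Sinv_d)) / T2
  f <- 1 / (w1^2 / (n1 - 1) + w2^2 / (n2 - 1))
  df2 <- f - p + 1
  Fstat <- T2 * df2 / (f * p)
  tibble(T2 = T2, df1 = p, df2 = df2,
         p_value = stats::pf(Fstat, p, df2, lower.tail = FALSE))
}

rcond_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) 0 else min(abs(e)) / max(abs(e))
}
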