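## Strain estimation from tracked cell positions: affine least squares,
## polar decomposition, strain-axis assignment and diagnostics.

# 180-degree-periodic angular distance between orientations (degrees).
circ_dist180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) {
    cols <- intersect(c("x_um", "y_um"), names(p))
    p <- if (length(cols) == 2) as.matrix(p[, cols]) else as.matrix(p[, 1:2])
  }
  storage.mode(p) <- "double"
  p
}

#' Rotate points into the OLM plane (sample-tilt correction)
#'
#' Applies the rigid rotation that maps the OLM plane normal onto the
#' out-of-plane axis, returning in-plane coordinates. 2D input points are
#' lifted onto the tilt plane first, so the correction restores true in-plane
#' distances; with a vertical normal the points are returned unchanged.
#'
#' @param points n x 2 or n x 3 matrix / data frame of positions (um).
#' @param tilt_plane list with `normal` (unit 3-vector) and `offset_um`
#'   (signed distance of the plane from the origin along the normal), as
#'   returned by [estimate_tilt()].
#' @return n x 2 matrix of in-plane coordinates (um).
#' @export
correct_tilt <- function(points, tilt_plane) {
  n <- tilt_plane$normal
  if (length(n) != 3 || abs(sqrt(sum(n^2)) - 1) > 1e-6) {
    abort("tilt_plane$normal must be a unit 3-vector.")
  }
  if (n[3] <= 1e-8) abort("Degenerate tilt plane: normal has no out-of-plane component.")
  p <- if (is.data.frame(points)) as.matrix(points[, intersect(c("x_um", "y_um", "z_um"),
                                                               names(points))]) else as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) == 2) {
    off <- tilt_plane$offset_um %||% 0
    z <- (off - p[, 1] * n[1] - p[, 2] * n[2]) / n[3]
    p <- cbind(p, z)
  }
  ez <- c(0, 0, 1)
  v <- c(n[2] * ez[3] - n[3] * ez[2], n[3] * ez[1] - n[1] * ez[3], n[1] * ez[2] - n[2] * ez[1])
  s2 <- sum(v^2); c_ <- sum(n * ez)
  R <- if (s2 < 1e-24) diag(3) else {
    Vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + Vx + Vx %*% Vx * ((1 - c_) / s2)
  }
  out <- p %*% t(R)
  out[, 1:2, drop = FALSE]
}

#' Least-squares affine fit of a point correspondence
#'
#' Finds the affine transformation `rf_hat = M r0 + b` minimizing the summed
#' squared deviation from the observed positions `rf`, solved in closed form
#' on mean-centered coordinates (the translation is recovered from the
#' centroids).
#'
#' @param r0 pre-deformation positions, n x 2 (matrix or data frame with
#'   `x_um`, `y_um`); n >= 3, non-collinear.
#' @param rf positions of the same points after deformation, same order.
#' @return Object of class `affine_fit`: list with `M` (2 x 2), `b`
#'   (2-vector), `residual_rms` (um), `n`.
#' @export
fit_affine <- function(r0, rf) {
  r0 <- as_point_matrix(r0); rf <- as_point_matrix(rf)
  if (nrow(r0) != nrow(rf)) abort("Point correspondence requires equal counts.")
  if (nrow(r0) < 3) abort("At least 3 point pairs are required.")
  c0 <- colMeans(r0); cf <- colMeans(rf)
  A <- sweep(r0, 2, c0); B <- sweep(rf, 2, cf)
  S00 <- crossprod(A)                   # sum r0c r0c^T
  sv <- svd(S00)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1)) {
    abort("Pre-ablation points are (nearly) collinear; affine fit is rank deficient.",
          class = "mosaicmech_rank_error")
  }
  M <- t(solve(S00, crossprod(A, B)))   # Sf0 %*% S00^-1
  dimnames(M) <- NULL
  b <- as.numeric(cf - M %*% c0)
  res <- rf - (r0 %*% t(M) + matrix(b, nrow(r0), 2, byrow = TRUE))
  structure(list(M = M, b = b,
                 residual_rms = sqrt(mean(rowSums(res^2))),
                 n = nrow(r0)),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("affine_fit (n = %d): residual RMS %.4g um\nM =\n", x$n, x$residual_rms))
  print(round(x$M, 6)); cat("b =", round(x$b, 6), "\n")
  invisible(x)
}

#' Residual displacement as a fraction of the neighbor distance
#'
#' RMS of the residuals `rf - (M r0 + b)` divided by a typical neighboring
#' cell distance; small values indicate that the observed deformation is
#' well described as affine.
#'
#' @param r0,rf point correspondence as in [fit_affine()].
#' @param fit an `affine_fit`.
#' @param neighbor_dist typical neighboring cell distance (um), e.g. from
#'   [typical_neighbor_distance()].
#' @return Dimensionless fraction.
#' @export
residual_fraction <- function(r0, rf, fit, neighbor_dist) {
  if (neighbor_dist <= 0) abort("`neighbor_dist` must be positive.")
  r0 <- as_point_matrix(r0); rf <- as_point_matrix(rf)
  res <- rf - (r0 %*% t(fit$M) + matrix(fit$b, nrow(r0), 2, byrow = TRUE))
  sqrt(mean(rowSums(res^2))) / neighbor_dist
}

#' Typical neighboring cell distance
#'
#' Median over all points of the distance to the nearest other point.
#'
#' @param points n x 2 positions (um), n >= 2.
#' @return Median nearest-neighbor distance (um).
#' @export
typical_neighbor_distance <- function(points) {
  p <- as_point_matrix(points)
  if (nrow(p) < 2) abort("At least 2 points are required.")
  D <- as.matrix(stats::dist(p))
  diag(D) <- Inf
  median(apply(D, 1, min))
}

#' Polar decomposition of a 2x2 deformation gradient
#'
#' Factors `M = U P` with `U` orthogonal (the rigid rotation) and
#' `P = (M^T M)^(1/2)` symmetric positive semi-definite (the pure stretch),
#' computed from the eigendecomposition of `M^T M`. A singular `M` is handled
#' with the pseudo-inverse and flagged.
#'
#' @param M finite 2 x 2 matrix.
#' @return Object of class `polar_decomposition`: list with `U`, `P`,
#'   `eigenvalues` (stretches, decreasing), `eigenvectors` (columns, unit),
#'   `singular` flag.
#' @export
polar_decompose <- function(M) {
  if (!all(is.finite(M)) || !all(dim(M) == c(2, 2))) abort("M must be a finite 2x2 matrix.")
  e <- eigen(crossprod(M), symmetric = TRUE)
  lam <- sqrt(pmax(e$values, 0))
  P <- e$vectors %*% diag(lam) %*% t(e$vectors)
  singular <- lam[2] <= 1e-12 * max(lam[1], 1)
  inv_lam <- ifelse(lam > 1e-12 * max(lam[1], 1), 1 / lam, 0)
  U <- M %*% (e$vectors %*% diag(inv_lam) %*% t(e$vectors))
  if (singular) {
    # complete U to a proper orthogonal matrix via its SVD
    s <- svd(U); U <- s$u %*% t(s$v)
  }
  structure(list(U = U, P = P, eigenvalues = lam, eigenvectors = e$vectors,
                 singular = singular),
            class = "polar_decomposition")
}

#' Assign stretch eigenvalues to the column axes
#'
#' Given the pure-stretch factor `P` and the cone column direction, the
#' eigenvector closer (180-degree-periodic) to the column direction carries
#' the y-strain (stretch parallel to the columns); the other eigenvector
#' carries the x-strain (perpendicular). The angular deviation of the
#' y-assigned eigenvector from the column direction is reported.
#'
#' @param P symmetric positive semi-definite 2 x 2 matrix, or a
#'   `polar_decomposition`.
#' @param theta_c_deg column direction in degrees (numeric, or a
#'   `column_direction` object from [estimate_column_direction()]).
#' @return One-row tibble: `x_strain`, `y_strain`, `axis_deviation_deg`,
#'   `indeterminate` (TRUE when `P` is isotropic and the axes are arbitrary).
#' @export
strain_axes <- function(P, theta_c_deg) {
  if (inherits(P, "polar_decomposition")) P <- P$P
  if (inherits(theta_c_deg, "column_direction")) theta_c_deg <- theta_c_deg$theta_c_deg
  if (max(abs(P - t(P))) > 1e-8 * max(abs(P), 1)) abort("P must be symmetric.")
  e <- eigen(P, symmetric = TRUE)
  ang <- (atan2(e$vectors[2, ], e$vectors[1, ]) * 180 / pi) %% 180
  indeterminate <- abs(e$values[1] - e$values[2]) <= 1e-12 * max(abs(e$values[1]), 1)
  dev <- circ_dist180(ang, theta_c_deg)
  iy <- which.min(dev)
  tibble(x_strain = e$values[-iy][1], y_strain = e$values[iy],
         axis_deviation_deg = if (indeterminate) NA_real_ else dev[iy],
         indeterminate = indeterminate)
}

#' Run the full strain-estimation pipeline on an ablation experiment
#'
#' For every post-ablation timepoint: optional sample-tilt correction, affine
#' least-squares fit, polar decomposition, strain-axis assignment relative to
#' the column direction, and the residual fraction relative to the typical
#' neighboring cell distance.
#'
#' @param experiment an `ablation_experiment` (or a list with `points_pre`,
#'   `points_post`, `times_min`, `group`).
#' @param theta_c_deg column direction (degrees or `column_direction`).
#' @param tilt_plane optional tilt plane (see [correct_tilt()]) applied to
#'   all positions before fitting.
#' @return Tibble of class `strain_table`: one row per timepoint with
#'   `time_min`, `group`, `x_strain`, `y_strain`, `axis_deviation_deg`,
#'   `rotation_deg` (rigid rotation from `U`), `residual_fraction`,
#'   `neighbor_dist_um`, `n_points`. The per-timepoint `affine_fit` objects
#'   are attached as attribute `fits`.
#' @export
run_strain_experiment <- function(experiment, theta_c_deg = 90, tilt_plane = NULL) {
  r0 <- as_point_matrix(experiment$points_pre)
  if (!is.null(tilt_plane)) r0 <- correct_tilt(r0, tilt_plane)
  nd <- typical_neighbor_distance(r0)
  fits <- list()
  rows <- purrr::map_dfr(seq_along(experiment$times_min), function(k) {
    rf <- as_point_matrix(experiment$points_post[[k]])
    if (!is.null(tilt_plane)) rf <- correct_tilt(rf, tilt_plane)
    fit <- fit_affine(r0, rf)
    fits[[k]] <<- fit
    pd <- polar_decompose(fit$M)
    ax <- strain_axes(pd, theta_c_deg)
    tibble(time_min = experiment$times_min[k],
           group = experiment$group %||% "ABLATION",
           x_strain = ax$x_strain, y_strain = ax$y_strain,
           axis_deviation_deg = ax$axis_deviation_deg,
           rotation_deg = atan2(pd$U[2, 1], pd$U[1, 1]) * 180 / pi,
           residual_fraction = residual_fraction(r0, rf, fit, nd),
           neighbor_dist_um = nd,
           n_points = fit$n)
  })
  structure(rows, class = c("strain_table", class(rows)), fits = fits)
}

#' Compare pooled strains between ablation and control groups
#'
#' Pools all post-ablation timepoints within each group and compares the
#' groups with Welch's unequal-variance t test on the x- and y-strains
#' separately and with the unequal-covariance Hotelling T-squared test on
#' the (x, y) strain pairs jointly.
#'
#' @param ablation,control `strain_table` tibbles (or any tibbles with
#'   `x_strain`, `y_strain`).
#' @return Tibble with one row per test: `test`, `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
compare_strain_groups <- function(ablation, control) {
  wx <- welch_t_test(ablation$x_strain, control$x_strain)
  wy <- welch_t_test(ablation$y_strain, control$y_strain)
  ht <- hotelling_unequal(cbind(ablation$x_strain, ablation$y_strain),
                          cbind(control$x_strain, control$y_strain))
  tibble(test = c("welch_x_strain", "welch_y_strain", "hotelling_xy"),
         statistic = c(wx$t, wy$t, ht$T2),
         df1 = c(wx$df, wy$df, ht$df1),
         df2 = c(NA_real_, NA_real_, ht$df2),
         p_value = c(wx$p_value, wy$p_value, ht$p_value))
}

## ---- broom-style methods --------------------------------------------------

#' Tidy an affine fit
#'
#' @param x an `affine_fit`.
#' @param ... unused.
#' @return Tibble with one row per affine coefficient (`M[i,j]`, `b[i]`).
#' @export
tidy.affine_fit <- function(x, ...) {
  tibble(term = c("M[1,1]", "M[1,2]", "M[2,1]", "M[2,2]", "b[1]", "b[2]"),
         estimate = c(x$M[1, 1], x$M[1, 2], x$M[2, 1], x$M[2, 2], x$b))
}

#' One-row summary of an affine fit
#'
#' @param x an `affine_fit`.
#' @param ... unused.
#' @return Tibble with `n`, `residual_rms`, `det_M`.
#' @export
glance.affine_fit <- function(x, ...) {
  tibble(n = x$n, residual_rms = x$residual_rms, det_M = det(x$M))
}

#' Tidy a polar decomposition
#'
#' @param x a `polar_decomposition`.
#' @param ... unused.
#' @return Tibble with one row per principal stretch: `stretch`,
#'   `angle_deg` of its eigenvector (mod 180).
#' @export
tidy.polar_decomposition <- function(x, ...) {
  tibble(stretch = x$eigenvalues,
         angle_deg = (atan2(x$eigenvectors[2, ], x$eigenvectors[1, ]) * 180 / pi) %% 180)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
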