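rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

test_that("polar decomposition handles canonical cases", {
  pd <- polar_decompose(diag(2))
  expect_equal(pd$U, diag(2), tolerance = 1e-12)
  expect_equal(pd$P, diag(2), tolerance = 1e-12)
  M <- rot2(30) %*% diag(c(1.3, 0.8))
  pd2 <- polar_decompose(M)
  expect_equal(pd2$U, rot2(30), tolerance = 1e-10)
  expect_equal(sort(pd2$eigenvalues), c(0.8, 1.3), tolerance = 1e-10)
})

test_that("polar decomposition passes the SVD oracle on random matrices", {
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    M <- matrix(stats::rnorm(4), 2, 2)
    pd <- polar_decompose(M)
    s <- svd(M)
    P_oracle <- s$v %*% diag(s$d) %*% t(s$v)
    worst <- max(worst,
                 max(abs(pd$U %*% pd$P - M)),
                 max(abs(crossprod(pd$U) - diag(2))),
                 max(abs(pd$P - t(pd$P))),
                 max(abs(pd$P - P_oracle)),
                 abs(prod(pd$eigenvalues) - abs(det(M))),
                 -min(eigen(pd$P, symmetric = TRUE)$values))
  }
  expect_lt(worst, 1e-10)
})

test_that("singular deformations are flagged and still factor", {
  pd <- polar_decompose(matrix(c(1, 0, 0, 0), 2, 2))
  expect_true(pd$singular)
  expect_equal(pd$U %*% pd$P, matrix(c(1, 0, 0, 0), 2, 2), tolerance = 1e-10)
  expect_equal(crossprod(pd$U), diag(2), tolerance = 1e-10)
})

test_that("affine fitting is exact on noise-free data", {
  set.seed(8)
  r0 <- cbind(stats::runif(15, 0, 20), stats::runif(15, 0, 20))
  fit_id <- fit_affine(r0, r0)
  expect_equal(fit_id$M, diag(2), tolerance = 1e-12)
  expect_equal(fit_id$b, c(0, 0), tolerance = 1e-12)
  M0 <- matrix(c(1.2, 0, 0, 0.9), 2, 2); b0 <- c(0.5, -0.3)
  rf <- r0 %*% t(M0) + matrix(b0, 15, 2, byrow = TRUE)
  fit <- fit_affine(r0, rf)
  expect_equal(fit$M, M0, tolerance = 1e-12)
  expect_equal(fit$b, b0, tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-12)
})

test_that("the noisy fit beats random perturbations of (M, b)", {
  set.seed(21)
  r0 <- cbind(stats::runif(20, 0, 20), stats::runif(20, 0, 20))
  rf <- r0 %*% t(matrix(c(1.1, 0.05, -0.02, 0.95), 2, 2)) +
    matrix(stats::rnorm(40, sd = 0.3), 20, 2)
  fit <- fit_affine(r0, rf)
  obj <- function(M, b) sum((rf - r0 %*% t(M) - matrix(b, 20, 2, byrow = TRUE))^2)
  obj_fit <- obj(fit$M, fit$b)
  beaten <- vapply(seq_len(1e4), function(i) {
    obj(fit$M + matrix(stats::rnorm(4, sd = 0.01), 2, 2),
        fit$b + stats::rnorm(2, sd = 0.05)) >= obj_fit
  }, logical(1))
  expect_true(all(beaten))
})

test_that("collinear or undersized point sets are rejected", {
  line_pts <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine(line_pts, line_pts), class = "mosaicmech_rank_error")
  expect_error(fit_affine(cbind(1:2, 1:2), cbind(1:2, 1:2)))
})

test_that("residual fraction reflects constructed displacements", {
  r0 <- as.matrix(expand.grid(x_um = 0:4, y_um = 0:4))
  fit <- fit_affine(r0, r0)
  expect_equal(residual_fraction(r0, r0, fit, 1), 0)
  eps <- 0.25
  shifted <- r0 + cbind(rep(c(eps, -eps), length.out = 25), 0)
  fit_s <- list(M = diag(2), b = c(0, 0))
  expect_equal(residual_fraction(r0, shifted, fit_s, 1), eps)
  # monotone in simulation noise
  lat <- generate_mosaic_lattice(3, 2)
  fr <- vapply(c(0, 0.05, 0.15), function(ns) {
    e <- simulate_ablation_recoil(lat, strain_true = c(1, 1.1), noise_sd = ns,
                                  times_min = 60, seed = 2)
    st <- run_strain_experiment(e, 90)
    st$residual_fraction
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("typical neighbor distance is the median nearest-neighbor gap", {
  grid <- as.matrix(expand.grid(0:3, 0:3))
  expect_equal(typical_neighbor_distance(grid), 1)
  expect_equal(typical_neighbor_distance(grid * 3.5), 3.5)
  lat <- generate_mosaic_lattice(3, 3)
  expect_equal(typical_neighbor_distance(lat[lat$subtype != "ROD", c("x_um", "y_um")]),
               attr(lat, "spacing"))
  expect_error(typical_neighbor_distance(cbind(1, 1)))
})

test_that("strain axes assign eigenvalues relative to the columns", {
  ax <- strain_axes(diag(c(1.0, 1.2)), 90)
  expect_equal(ax$x_strain, 1.0)
  expect_equal(ax$y_strain, 1.2)
  expect_equal(ax$axis_deviation_deg, 0)
  # rotating P and theta_c together leaves strains unchanged
  for (delta in c(20, 75)) {
    P <- rot2(delta) %*% diag(c(1.0, 1.2)) %*% t(rot2(delta))
    ax2 <- strain_axes(P, (90 + delta) %% 180)
    expect_equal(ax2$x_strain, 1.0, tolerance = 1e-10)
    expect_equal(ax2$y_strain, 1.2, tolerance = 1e-10)
    expect_equal(ax2$axis_deviation_deg, 0, tolerance = 1e-6)
  }
  iso <- strain_axes(diag(c(1.1, 1.1)), 90)
  expect_true(iso$indeterminate)
  expect_equal(iso$x_strain, 1.1)
})

test_that("strain eigenvalues are invariant under a common rigid rotation", {
  set.seed(3)
  r0 <- cbind(stats::runif(15, 0, 20), stats::runif(15, 0, 20))
  rf <- r0 %*% t(rot2(10) %*% diag(c(0.95, 1.2)))
  R <- rot2(33)
  ev1 <- polar_decompose(fit_affine(r0, rf)$M)$eigenvalues
  ev2 <- polar_decompose(fit_affine(r0 %*% t(R), rf %*% t(R))$M)$eigenvalues
  expect_equal(ev1, ev2, tolerance = 1e-10)
})

test_that("tilt correction is exact and reduces to identity when flat", {
  pts <- cbind(stats::runif(10, 0, 30), stats::runif(10, 0, 30))
  flat <- list(normal = c(0, 0, 1), offset_um = 4)
  expect_equal(correct_tilt(pts, flat), pts, ignore_attr = TRUE)
  n <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  tp <- list(normal = n, offset_um = 5)
  z <- (5 - pts[, 1] * n[1] - pts[, 2] * n[2]) / n[3]
  corrected <- correct_tilt(pts, tp)
  expect_equal(as.numeric(stats::dist(corrected)),
               as.numeric(stats::dist(cbind(pts, z))), tolerance = 1e-9)
  expect_error(correct_tilt(pts, list(normal = c(1, 0, 0), offset_um = 0)))
})

test_that("the full pipeline recovers simulated recoil exactly at zero noise", {
  lat <- generate_mosaic_lattice(3, 3)
  ctrl <- simulate_ablation_recoil(lat, group = "CONTROL", noise_sd = 0,
                                   times_min = c(10, 30))
  st_c <- run_strain_experiment(ctrl, 90)
  expect_equal(st_c$x_strain, c(1, 1), tolerance = 1e-12)
  expect_equal(st_c$y_strain, c(1, 1), tolerance = 1e-12)
  abl <- simulate_ablation_recoil(lat, strain_true = c(1.0, 1.2), noise_sd = 0,
                                  times_min = c(10, 60))
  st_a <- run_strain_experiment(abl, 90)
  expect_equal(st_a$x_strain[2], 1.0, tolerance = 1e-10)
  expect_equal(st_a$y_strain[2], 1.2, tolerance = 1e-10)
  expect_equal(st_a$axis_deviation_deg[2], 0, tolerance = 1e-6)
  # truth with rotation and stretch round-trips through the pipeline
  rotated <- simulate_ablation_recoil(lat, strain_true = c(0.95, 1.25),
                                      rotation_deg = 18, noise_sd = 0, times_min = 60)
  st_r <- run_strain_experiment(rotated, 90)
  expect_equal(st_r$x_strain, 0.95, tolerance = 1e-10)
  expect_equal(st_r$y_strain, 1.25, tolerance = 1e-10)
  expect_equal(st_r$rotation_deg, 18, tolerance = 1e-8)
})

test_that("axis assignment tolerates a jittered column direction", {
  lat <- generate_mosaic_lattice(3, 3)
  spacing <- attr(lat, "spacing")
  set.seed(17)
  ok <- vapply(1:50, function(s) {
    e <- simulate_ablation_recoil(lat, strain_true = c(1.0, 1.2),
                                  noise_sd = 0.02 * spacing, times_min = 60, seed = s)
    st <- run_strain_experiment(e, 90 + stats::runif(1, -10, 10))
    st$axis_deviation_deg <= 20
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("tidy and glance methods expose the fitted quantities", {
  set.seed(5)
  r0 <- cbind(stats::runif(10, 0, 10), stats::runif(10, 0, 10))
  fit <- fit_affine(r0, r0 %*% t(diag(c(1.1, 0.9))))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "M[1,1]"], 1.1, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$det_M, 1.1 * 0.9, tolerance = 1e-10)
  pd <- polar_decompose(fit$M)
  expect_equal(sort(tidy(pd)$stretch), c(0.9, 1.1), tolerance = 1e-10)
})
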