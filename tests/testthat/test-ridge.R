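test_that("a constant image has (near) zero ridge score", {
  rf <- steerable_ridge_filter(matrix(1, 48, 48), 4, 8)
  expect_lt(max(abs(rf$score)), 1e-9)
})

test_that("a straight line is detected at its orientation", {
  img <- line_image(96, 96, 30)
  rf <- steerable_ridge_filter(img, 4, 8)
  lines <- refine_ridges(rf, score_quantile = 0.9)
  px <- tidyr::unnest(dplyr::select(lines, pixels), pixels)
  expect_gt(nrow(px), 30)
  # surviving centerline pixels sit on the line and carry its angle
  d <- abs(-(px$col - 48) * sin(pi / 6) + (px$row - 48) * cos(pi / 6))
  expect_lt(max(d), 2)
  ang <- rf$angle_deg[cbind(px$row, px$col)]
  expect_lt(max(circ_dist(ang, 30)), 5)
})

test_that("the optimal angle is rotation-equivariant", {
  for (delta in c(15, 40)) {
    img <- line_image(96, 96, 30 + delta)
    rf <- steerable_ridge_filter(img, 4, 8)
    sel <- rf$score >= stats::quantile(rf$score, 0.98)
    ang <- rf$angle_deg[sel]
    # circular mean of doubled angles
    m <- (atan2(mean(sin(ang * pi / 90)), mean(cos(ang * pi / 90))) * 90 / pi) %% 180
    expect_lt(circ_dist(m, 30 + delta), 3)
  }
})

test_that("small images and invalid orders are rejected", {
  expect_error(steerable_ridge_filter(matrix(0, 10, 10), 4, 8),
               class = "mosaicmech_sizing_error")
  expect_error(steerable_ridge_filter(matrix(0, 48, 48), order = 3))
  expect_error(steerable_ridge_filter(matrix(0, 48, 48), order = 0))
})

test_that("refinement removes salt noise but keeps the line", {
  img <- line_image(80, 80, 90, width_px = 6)
  set.seed(12)
  salt <- sample(which(img < 0.01), 25)
  img[salt] <- 1
  rf <- steerable_ridge_filter(img, 4, 8)
  lines <- refine_ridges(rf, score_quantile = 0.9, min_neighbors = 2)
  long <- lines[lines$length_px >= 10, ]
  expect_equal(nrow(long), 1)
  expect_lt(circ_dist(long$mean_angle_deg, 90), 5)
  # line pixels hug the true centerline column
  px <- long$pixels[[1]]
  expect_lt(max(abs(px$col - 40)), 2)
})

test_that("an all-zero field refines to an empty result", {
  rf <- structure(list(score = matrix(0, 40, 40), angle_deg = matrix(0, 40, 40),
                       order = 4, width_px = 8), class = "ridge_field")
  expect_equal(nrow(refine_ridges(rf)), 0)
})

test_that("raising the score quantile never adds ridge pixels", {
  img <- line_image(80, 80, 45)
  rf <- steerable_ridge_filter(img, 4, 8)
  nms <- mosaicmech:::nms_across_ridge(rf$score, rf$angle_deg)
  surv_at <- function(q) which(rf$score >= stats::quantile(rf$score, q) & nms)
  lo <- surv_at(0.80); hi <- surv_at(0.95)
  expect_true(all(hi %in% lo))
  # and the linked output never grows either
  n_px <- function(q) sum(refine_ridges(rf, score_quantile = q)$length_px)
  expect_lte(n_px(0.95), n_px(0.80))
})

test_that("spectral estimation recovers grating orientations", {
  n <- 96
  stripes_y <- matrix(sin(2 * pi * col(matrix(0, n, n)) / 12), n, n)
  cd <- estimate_column_direction(stripes_y)
  expect_lt(circ_dist(cd$theta_c_deg, 90), 2)
  expect_false(cd$low_confidence)
  # rotated grating shifts theta_c accordingly
  g <- expand.grid(row = 1:n, col = 1:n)
  for (ang in c(30, 120)) {
    th <- ang * pi / 180
    u <- g$col * cos(th - pi / 2) + g$row * sin(th - pi / 2)
    img <- matrix(sin(2 * pi * u / 12), n, n)
    cdr <- estimate_column_direction(img)
    expect_lt(circ_dist(cdr$theta_c_deg, ang), 2)
  }
})

test_that("flat and isotropic images are flagged", {
  expect_error(estimate_column_direction(matrix(3, 64, 64)),
               class = "mosaicmech_geometry_error")
  set.seed(5)
  wn <- matrix(stats::rnorm(96 * 96), 96, 96)
  expect_true(estimate_column_direction(wn)$low_confidence)
})

test_that("angular and length rules keep exactly the compliant lines", {
  theta_c <- 57
  lines <- toy_ridge_lines(theta_c + c(0, 45, 0, -20), c(25, 100, 15, 40))
  kept <- filter_ridges(lines, theta_c)
  expect_equal(kept$line_id, c(1L, 4L))
  # boundary behavior from the stated rules
  edge <- toy_ridge_lines(theta_c + c(30, 31), c(20, 20))
  kept2 <- filter_ridges(edge, theta_c)
  expect_equal(kept2$line_id, 1L)
  # 180-degree wraps do not change the outcome
  wrapped <- toy_ridge_lines(theta_c + c(0, 45, 0, -20) + 180, c(25, 100, 15, 40))
  expect_equal(filter_ridges(wrapped, theta_c)$line_id, c(1L, 4L))
  expect_equal(filter_ridges(lines, theta_c + 180)$line_id, c(1L, 4L))
})

test_that("ridge statistics match brute-force aggregation", {
  theta_c <- 90
  lines <- toy_ridge_lines(c(92, 80, 100), c(30, 22, 45))
  s <- ridge_statistics(lines, theta_c)
  expect_equal(s$summary$n_lines, 3)
  expect_equal(s$summary$total_length_px, 97)
  expect_equal(s$summary$mean_abs_deviation_deg, mean(c(2, 10, 10)))
  expect_equal(sum(s$histogram$total_length_px), 97)
  one <- ridge_statistics(toy_ridge_lines(75, 30), theta_c)
  expect_equal(one$summary$mean_abs_deviation_deg, 15)
  none <- ridge_statistics(toy_ridge_lines(numeric(0), numeric(0)), theta_c)
  expect_equal(none$summary$n_lines, 0)
})

test_that("glial-band ridges run between columns; the rotated control fails", {
  lat <- generate_mosaic_lattice(5, 4)
  gb <- render_glial_band_image(lat, band_width_px = 8, lamella_width_px = 2)
  cd <- estimate_column_direction(gb)
  lines <- refine_ridges(steerable_ridge_filter(gb, 4, 8))
  kept <- filter_ridges(lines, cd)
  expect_gte(nrow(kept), length(column_centerlines(lat)$v_mid) - 1)
  px <- tidyr::unnest(dplyr::select(kept, line_id, pixels), pixels)
  cl <- column_centerlines(lat)
  x <- gb$origin_um[1] + (px$col - 0.5) * gb$pixel_size_um
  y <- gb$origin_um[2] + (px$row - 0.5) * gb$pixel_size_um
  v <- x * cl$e_v[1] + y * cl$e_v[2]
  dmin <- vapply(v, function(vi) min(abs(vi - cl$v_mid)), numeric(1))
  expect_lt(mean(dmin) / gb$pixel_size_um, 2)
  # negative control: same procedure with the perpendicular direction
  ctrl <- filter_ridges(lines, (cd$theta_c_deg + 90) %% 180)
  expect_lte(nrow(ctrl), 0.1 * nrow(kept))
})
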