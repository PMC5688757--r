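flat_stack <- function() {
  fixture("flat_stack", function() {
    lat <- generate_mosaic_lattice(3, 2)
    render_zstack(lat, surface_spec = list(mode = "flat", z0 = 10), nz = 12)
  })
}

test_that("a noise-free bright plane is recovered within half a z-step", {
  surf <- reconstruct_olm_surface(flat_stack(), "zo1")
  expect_lt(max(abs(surf$z_um - 10)), 0.9)
})

test_that("the all-zero channel is rejected", {
  stack <- flat_stack()
  stack$channels$zo1[] <- 0
  expect_error(reconstruct_olm_surface(stack, "zo1"), "zero")
  expect_error(reconstruct_olm_surface(flat_stack(), "nope"), "channel")
})

test_that("surface estimate is z-shift equivariant", {
  stack <- flat_stack()
  shift <- 2L
  arr <- stack$channels$zo1
  nz <- dim(arr)[1]
  arr2 <- array(0, dim(arr))
  arr2[(1 + shift):nz, , ] <- arr[1:(nz - shift), , ]
  stack2 <- stack
  stack2$channels$zo1 <- arr2
  s1 <- reconstruct_olm_surface(stack, "zo1")
  s2 <- reconstruct_olm_surface(stack2, "zo1")
  dz <- stack$voxel_size_um[1]
  expect_lt(max(abs(s2$z_um - (s1$z_um + shift * dz))), 1e-3)
})

test_that("masked pixels are interpolated to within one z-step of truth", {
  lat <- generate_mosaic_lattice(3, 2)
  sl <- c(0.1, 0.05)
  stack <- render_zstack(lat, surface_spec = list(mode = "tilted", z0 = 14, slope = sl),
                         nz = 14)
  surf0 <- reconstruct_olm_surface(stack, "zo1")
  set.seed(4)
  mask <- matrix(stats::runif(length(surf0$z_um)) < 0.3, nrow(surf0$z_um))
  surf <- reconstruct_olm_surface(stack, "zo1", mask = mask)
  g <- pixel_grid(nrow(surf$z_um), ncol(surf$z_um), surf$pixel_size_um, surf$origin_um)
  ztrue <- surface_depth(g$x, g$y, list(mode = "tilted", z0 = 14, slope = sl))
  expect_lt(max(abs(surf$z_um - ztrue)), 1.8)
})

test_that("projection reproduces a surface-confined signal and respects the band", {
  stack <- flat_stack()
  surf <- reconstruct_olm_surface(stack, "zo1")
  pr <- project_at_surface(stack, "red", surf, band_halfwidth_um = 2, reducer = "max")
  # the brightest in-band slice is the signal layer itself
  k_best <- which.min(abs((seq_len(dim(stack$channels$red)[1]) - 0.5) * 1.8 - 10))
  expect_equal(pr$image, stack$channels$red[k_best, , ], tolerance = 1e-9)

  # a blob far below the surface must not appear in a narrow band
  stack2 <- stack
  stack2$channels$red[1, 10, 10] <- 100   # z ~ 0.9 um, surface at 10 um
  pr2 <- project_at_surface(stack2, "red", surf, band_halfwidth_um = 2, reducer = "max")
  expect_lt(pr2$image[10, 10], 1)

  # reducers are ordered pixelwise
  pmax_ <- project_at_surface(stack, "zo1", surf, 3, "max")
  pmean <- project_at_surface(stack, "zo1", surf, 3, "mean")
  expect_true(all(pmax_$image - pmean$image >= -1e-12))
})

test_that("shape mismatches between surface and stack are rejected", {
  stack <- flat_stack()
  surf <- reconstruct_olm_surface(stack, "zo1")
  surf$z_um <- surf$z_um[-1, ]
  expect_error(project_at_surface(stack, "zo1", surf),
               class = "mosaicmech_geometry_error")
})

test_that("tilt of a constructed plane is recovered in closed form", {
  g <- pixel_grid(40, 50, 0.5, c(0, 0))
  a <- 0.08; b <- -0.03; c0 <- 12
  surf <- make_surface_map(a * g$x + b * g$y + c0, pixel_size_um = 0.5)
  tp <- estimate_tilt(surf)
  expect_equal(tp$slope, c(a, b), tolerance = 1e-6)
  n_true <- c(-a, -b, 1) / sqrt(a^2 + b^2 + 1)
  expect_equal(tp$normal, n_true, tolerance = 1e-6)

  flat <- estimate_tilt(make_surface_map(matrix(5, 30, 30)))
  expect_equal(flat$normal, c(0, 0, 1), tolerance = 1e-9)
})

test_that("tilt of a noisy plane is recovered within 0.5 degree", {
  g <- pixel_grid(80, 80, 0.5, c(0, 0))
  a <- 0.15
  set.seed(2)
  z <- a * g$x + 8 + matrix(stats::rnorm(80 * 80, sd = 1.8), 80, 80)  # noise = 1 z-step
  tp <- estimate_tilt(make_surface_map(z, pixel_size_um = 0.5))
  expect_lt(abs(tp$tilt_deg - atan(a) * 180 / pi), 0.5)
})

test_that("tilted-stack reconstruction recovers the inclination", {
  lat <- generate_mosaic_lattice(3, 3)
  stack <- render_zstack(lat, surface_spec = list(mode = "tilted", z0 = 18,
                                                  slope = c(0.15, 0)), nz = 20)
  surf <- reconstruct_olm_surface(stack, "zo1")
  tp <- estimate_tilt(surf)
  expect_lt(abs(tp$tilt_deg - atan(0.15) * 180 / pi), 0.5)
})
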