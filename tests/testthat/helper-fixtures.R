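# Shared fixtures, built once per test run (rendering is the slow part).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# full simulate -> project -> segment -> classify pipeline on a noise-free
# ideal lattice; returns the positive:negative ratio tibble
pipeline_ratio <- function(include_rods, n_columns = 4, n_repeat_units = 4) {
  lat <- generate_mosaic_lattice(n_columns, n_repeat_units, include_rods = include_rods)
  stack <- render_zstack(lat, surface_spec = list(mode = "flat", z0 = 10))
  surf <- reconstruct_olm_surface(stack, "zo1")
  boundary <- project_at_surface(stack, "zo1", surf, band_halfwidth_um = 2, reducer = "max")
  reporter <- project_at_surface(stack, "red", surf, band_halfwidth_um = 2, reducer = "mean")
  segment_profiles(boundary, lat[, c("x_um", "y_um")]) |>
    measure_intensity(reporter) |>
    classify_kmeans() |>
    compute_ratio()
}

# surface_map built directly from a height field (bypassing reconstruction),
# for closed-form tilt tests
make_surface_map <- function(z_um, pixel_size_um = 0.5, origin_um = c(0, 0)) {
  structure(list(z_um = z_um,
                 confidence = matrix(1, nrow(z_um), ncol(z_um)),
                 valid = matrix(TRUE, nrow(z_um), ncol(z_um)),
                 voxel_size_um = c(1.8, pixel_size_um, pixel_size_um),
                 pixel_size_um = pixel_size_um, origin_um = origin_um,
                 smooth_sigma_px = 0, tilt_plane = NULL),
            class = "surface_map")
}

# synthetic image of a straight bright line through the image center at a
# given orientation, with Gaussian cross-profile of FWHM ~ width_px
line_image <- function(ny, nx, angle_deg, width_px = 8, amplitude = 1) {
  th <- angle_deg * pi / 180
  g <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  d <- abs(-(g$col - nx / 2) * sin(th) + (g$row - ny / 2) * cos(th))
  matrix(amplitude * exp(-0.5 * (d / (width_px / 2.355))^2), ny, nx)
}

# 180-degree-periodic angular distance
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# hand-built ridge_lines table for the filtering-rule tests
toy_ridge_lines <- function(angles_deg, lengths_px) {
  tibble::tibble(
    line_id = seq_along(angles_deg),
    length_px = as.integer(lengths_px),
    mean_angle_deg = angles_deg %% 180,
    mean_score = 1,
    pixels = lapply(lengths_px, function(L) tibble::tibble(row = seq_len(L), col = 1L)))
}
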