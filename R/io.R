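## File round-tripping (CSV tables, float TIFF images + JSON sidecars,
## JSON configs/manifests) and the pipeline runner functions.
##
## Conventions: positions in um, angles in degrees (counterclockwise from +x),
## pixel sizes explicit in every sidecar. TIFF stores [0, 1] floats; images
## are written normalized with the per-channel scale recorded in the sidecar
## and restored on read.

sidecar_path <- function(path) paste0(path, ".json")

read_json_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "mosaicmech_format_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Write / read a lattice as CSV plus JSON sidecar
#'
#' @param lattice a `mosaic_lattice`.
#' @param path CSV path; parameters go to `<path>.json`.
#' @return `write_lattice()` returns `path` invisibly; `read_lattice()`
#'   returns the `mosaic_lattice`.
#' @export
write_lattice <- function(lattice, path) {
  utils::write.csv(as.data.frame(lattice), path, row.names = FALSE)
  pars <- attributes(lattice)[c("spacing", "column_direction_deg", "column_gap_factor",
                                "rod_offset_factor", "n_columns", "n_repeat_units",
                                "include_rods", "jitter_sd")]
  write_json_file(pars, sidecar_path(path))
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "mosaicmech_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x_um", "y_um", "subtype", "column_index", "row_index")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Malformed lattice CSV %s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "mosaicmech_format_error")
  }
  pars <- read_json_file(sidecar_path(path))
  out <- as_tibble(df[, need])
  do.call(structure, c(list(out, class = c("mosaic_lattice", class(out))), pars))
}

#' Write / read an image stack as multi-page float TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...).
#'
#' @param stack an [image_stack].
#' @param path TIFF path; metadata goes to `<path>.json`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` the
#'   [image_stack].
#' @export
write_stack <- function(stack, path) {
  pages <- list(); scales <- numeric(0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    sc <- max(arr, 1e-12)
    scales[ch] <- sc
    for (k in seq_len(dim(arr)[1])) pages[[length(pages) + 1L]] <- arr[k, , ] / sc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  write_json_file(list(channels = names(stack$channels),
                       nz = dim(stack$channels[[1]])[1],
                       voxel_size_um = stack$voxel_size_um,
                       origin_um = stack$origin_um,
                       intensity_scale = as.list(scales)),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "mosaicmech_format_error")
  meta <- read_json_file(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$nz
  channels <- list()
  for (i in seq_along(meta$channels)) {
    ch <- meta$channels[i]
    sl <- pages[((i - 1) * nz + 1):(i * nz)]
    arr <- array(0, dim = c(nz, nrow(sl[[1]]), ncol(sl[[1]])))
    for (k in seq_len(nz)) arr[k, , ] <- sl[[k]] * meta$intensity_scale[[ch]]
    channels[[ch]] <- arr
  }
  image_stack(channels, voxel_size_um = unlist(meta$voxel_size_um),
              origin_um = unlist(meta$origin_um))
}

#' Write / read a 2D projection as float TIFF plus JSON sidecar
#'
#' @param proj a [projection2d].
#' @param path TIFF path.
#' @return `write_projection()` returns `path` invisibly;
#'   `read_projection()` the [projection2d].
#' @export
write_projection <- function(proj, path) {
  sc <- max(proj$image, 1e-12)
  tiff::writeTIFF(proj$image / sc, path, bits.per.sample = 32, reduce = FALSE)
  write_json_file(list(source_channel = proj$source_channel,
                       pixel_size_um = proj$pixel_size_um,
                       origin_um = proj$origin_um,
                       band_halfwidth_um = proj$band_halfwidth_um,
                       intensity_scale = sc),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "mosaicmech_format_error")
  meta <- read_json_file(sidecar_path(path))
  img <- tiff::readTIFF(path) * meta$intensity_scale
  projection2d(img, meta$source_channel, meta$pixel_size_um,
               unlist(meta$origin_um),
               meta$band_halfwidth_um %||% NA_real_)
}

#' Write / read tracked centroids and the experiment description
#'
#' Centroids go to CSV (`point_id`, `time_min`, `x_um`, `y_um`; time 0 is
#' pre-ablation), the experiment metadata (group, times, hole, truth) to a
#' JSON file.
#'
#' @param experiment an `ablation_experiment`.
#' @param csv_path,json_path output paths.
#' @return `write_experiment()` returns `csv_path` invisibly;
#'   `read_experiment()` the `ablation_experiment`.
#' @export
write_experiment <- function(experiment, csv_path, json_path) {
  utils::write.csv(as.data.frame(as_tibble(experiment)), csv_path, row.names = FALSE)
  tr <- experiment$truth
  write_json_file(list(group = experiment$group,
                       times_min = experiment$times_min,
                       hole = experiment$hole,
                       truth = list(M_true = as.vector(tr$M_true),
                                    b_true = tr$b_true,
                                    noise_sd = tr$noise_sd,
                                    tau_min = tr$tau_min)),
                  json_path)
  invisible(csv_path)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(csv_path, json_path) {
  if (!file.exists(csv_path)) abort(sprintf("File not found: %s", csv_path),
                                    class = "mosaicmech_format_error")
  meta <- read_json_file(json_path)
  df <- utils::read.csv(csv_path)
  need <- c("point_id", "time_min", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Malformed centroid CSV %s: missing column(s) %s", csv_path,
                  paste(missing_cols, collapse = ", ")),
          class = "mosaicmech_format_error")
  }
  pre <- df[df$time_min == 0, ]
  pre <- pre[order(pre$point_id), ]
  post <- lapply(meta$times_min, function(t) {
    p <- df[df$time_min == t, ]
    p <- p[order(p$point_id), ]
    tibble(point_id = p$point_id, x_um = p$x_um, y_um = p$y_um)
  })
  structure(list(points_pre = tibble(point_id = pre$point_id,
                                     x_um = pre$x_um, y_um = pre$y_um),
                 points_post = post,
                 times_min = meta$times_min,
                 group = meta$group,
                 hole = meta$hole,
                 truth = list(M_true = matrix(unlist(meta$truth$M_true), 2, 2),
                              b_true = unlist(meta$truth$b_true),
                              noise_sd = meta$truth$noise_sd,
                              tau_min = meta$truth$tau_min)),
            class = "ablation_experiment")
}

## ---- configuration --------------------------------------------------------

#' Default pipeline configuration
#'
#' Every stage parameter with its default; a config loaded from JSON is
#' merged over these defaults, so partial configs are valid.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    lattice = list(n_columns = 4L, n_repeat_units = 4L, spacing = 2.5,
                   include_rods = FALSE, column_direction_deg = 90,
                   jitter_sd = 0, column_gap_factor = sqrt(3)),
    render = list(pixel_size_um = 0.2, dz_um = 1.8, psf_sigma_um = 0.9,
                  noise_sd = 0, margin_um = 1.25,
                  surface = list(mode = "flat", z0 = 10)),
    surface = list(channel = "zo1", z_kernel_sigma_um = 1.8,
                   xy_smooth_sigma_um = 0.6, confidence_floor = 0.1,
                   band_halfwidth_um = 2, reducer = "max"),
    segmentation = list(method = "exact"),
    ridge = list(order = 4L, width_px = 8L, score_quantile = 0.8,
                 min_neighbors = 1L, max_dev_deg = 30, min_length_px = 20L),
    recoil = list(hole_radius = 3, strain_true = c(1, 1.2), rotation_deg = 0,
                  translation = c(0, 0), times_min = c(5, 15, 30, 60),
                  noise_sd = 0.05, tau_min = 20),
    strain = list(theta_c_deg = 90)
  )
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON path.
#' @param config configuration list (see [default_config()]).
#' @return `read_config()` returns the config merged over the defaults;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- read_json_file(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  write_json_file(config, path)
  invisible(path)
}

validate_config <- function(config) {
  with(config$lattice, {
    if (n_columns < 1 || n_repeat_units < 1 || spacing <= 0 || jitter_sd < 0)
      abort("Invalid lattice config: sizes must be positive.",
            class = "mosaicmech_validation_error")
  })
  if (config$render$pixel_size_um <= 0 || config$render$dz_um <= 0)
    abort("Invalid render config: voxel sizes must be positive.",
          class = "mosaicmech_validation_error")
  if (config$ridge$score_quantile <= 0 || config$ridge$score_quantile >= 1)
    abort("Invalid ridge config: score_quantile must be in (0, 1).",
          class = "mosaicmech_validation_error")
  if (any(config$recoil$strain_true <= 0))
    abort("Invalid recoil config: stretches must be positive.",
          class = "mosaicmech_validation_error")
  invisible(config)
}

write_manifest <- function(out_dir, step, params, inputs, outputs) {
  # content hashes keyed by file name (not path), so reruns in different
  # directories produce byte-identical manifests
  hashes <- if (length(inputs))
    as.list(stats::setNames(unname(tools::md5sum(inputs)), basename(inputs))) else list()
  write_json_file(list(package = "mosaicmech",
                       version = as.character(utils::packageVersion("mosaicmech")),
                       step = step, parameters = params,
                       input_md5 = hashes, outputs = basename(outputs)),
                  file.path(out_dir, sprintf("manifest_%s.json", step)))
}

## ---- pipeline runners -----------------------------------------------------

#' Pipeline runners: simulate, project, segment, ridges, strain
#'
#' Reproducible file-to-file stages tying the modules together. Each runner
#' is a pure function of its inputs, the configuration and the master seed,
#' and writes a manifest JSON recording the package version, parameters and
#' input checksums next to its outputs.
#'
#' `run_simulate()` writes `lattice.csv`, `stack.tif` and recoil experiments
#' (`recoil_ablation.csv/.json`, `recoil_control.csv/.json`).
#' `run_project()` writes `surface.tif` (+ tilt in its sidecar) and one
#' `projection_<channel>.tif` per channel. `run_segment()` writes
#' `profiles.csv` and `ratio.json`. `run_ridges()` writes `ridge_lines.csv`,
#' `ridge_pixels.csv` and `ridge_report.json`. `run_strain()` writes
#' `strain.csv` and, when a control experiment is supplied, `stats.json`.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @param stack_path,boundary_path,reporter_path,seeds_path,image_path,points_path,experiment_path,control_points_path,control_experiment_path input file paths.
#' @return Named list of written paths, invisibly.
#' @name pipeline-runners
NULL

#' @rdname pipeline-runners
#' @export
run_simulate <- function(config = default_config(), out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lat <- do.call(generate_mosaic_lattice, c(config$lattice, list(seed = config$seed)))
  paths <- list(lattice = file.path(out_dir, "lattice.csv"),
                stack = file.path(out_dir, "stack.tif"))
  write_lattice(lat, paths$lattice)
  stack <- render_zstack(lat, surface_spec = config$render$surface,
                         psf_sigma_um = config$render$psf_sigma_um,
                         noise_sd = config$render$noise_sd,
                         seed = config$seed,
                         pixel_size_um = config$render$pixel_size_um,
                         dz_um = config$render$dz_um,
                         margin_um = config$render$margin_um)
  write_stack(stack, paths$stack)
  for (grp in c("ABLATION", "CONTROL")) {
    exp_ <- do.call(simulate_ablation_recoil,
                    c(list(lattice = lat, group = grp,
                           seed = config$seed + (grp == "CONTROL")),
                      config$recoil))
    base <- file.path(out_dir, paste0("recoil_", tolower(grp)))
    write_experiment(exp_, paste0(base, ".csv"), paste0(base, ".json"))
    paths[[paste0("recoil_", tolower(grp))]] <- paste0(base, ".csv")
  }
  write_manifest(out_dir, "simulate", config, character(0),
                 unlist(paths, use.names = FALSE))
  invisible(paths)
}

#' @rdname pipeline-runners
#' @export
run_project <- function(stack_path, config = default_config(), out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- read_stack(stack_path)
  sc <- config$surface
  surf <- reconstruct_olm_surface(stack, sc$channel,
                                  z_kernel_sigma_um = sc$z_kernel_sigma_um,
                                  xy_smooth_sigma_um = sc$xy_smooth_sigma_um,
                                  confidence_floor = sc$confidence_floor)
  tilt <- estimate_tilt(surf)
  surf_path <- file.path(out_dir, "surface.tif")
  tiff::writeTIFF(surf$z_um / max(surf$z_um), surf_path, bits.per.sample = 32)
  write_json_file(list(tilt_plane = tilt, z_scale_um = max(surf$z_um),
                       pixel_size_um = surf$pixel_size_um,
                       origin_um = surf$origin_um),
                  sidecar_path(surf_path))
  paths <- list(surface = surf_path)
  for (ch in names(stack$channels)) {
    proj <- project_at_surface(stack, ch, surf,
                               band_halfwidth_um = sc$band_halfwidth_um,
                               reducer = sc$reducer)
    p <- file.path(out_dir, sprintf("projection_%s.tif", ch))
    write_projection(proj, p)
    paths[[paste0("projection_", ch)]] <- p
  }
  write_manifest(out_dir, "project", config, stack_path,
                 unlist(paths, use.names = FALSE))
  invisible(paths)
}

#' @rdname pipeline-runners
#' @export
run_segment <- function(boundary_path, reporter_path, seeds_path,
                        config = default_config(), out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  boundary <- read_projection(boundary_path)
  reporter <- read_projection(reporter_path)
  if (!file.exists(seeds_path)) abort(sprintf("File not found: %s", seeds_path),
                                      class = "mosaicmech_format_error")
  seeds <- utils::read.csv(seeds_path)
  profs <- segment_profiles(boundary, seeds) |>
    measure_intensity(reporter) |>
    classify_kmeans(method = config$segmentation$method, seed = config$seed)
  ratio <- compute_ratio(profs)
  paths <- list(profiles = file.path(out_dir, "profiles.csv"),
                ratio = file.path(out_dir, "ratio.json"))
  utils::write.csv(as.data.frame(profs), paths$profiles, row.names = FALSE)
  write_json_file(as.list(ratio), paths$ratio)
  write_manifest(out_dir, "segment", config,
                 c(boundary_path, reporter_path, seeds_path),
                 unlist(paths, use.names = FALSE))
  invisible(paths)
}

#' @rdname pipeline-runners
#' @export
run_ridges <- function(image_path, config = default_config(), out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proj <- read_projection(image_path)
  rc <- config$ridge
  theta_c <- estimate_column_direction(proj)
  field <- steerable_ridge_filter(proj, order = rc$order, width_px = rc$width_px)
  lines <- refine_ridges(field, score_quantile = rc$score_quantile,
                         min_neighbors = rc$min_neighbors)
  kept <- filter_ridges(lines, theta_c, max_dev_deg = rc$max_dev_deg,
                        min_length_px = rc$min_length_px)
  stats_ <- ridge_statistics(kept, theta_c)
  paths <- list(lines = file.path(out_dir, "ridge_lines.csv"),
                pixels = file.path(out_dir, "ridge_pixels.csv"),
                report = file.path(out_dir, "ridge_report.json"))
  utils::write.csv(as.data.frame(select(kept, -"pixels")), paths$lines, row.names = FALSE)
  pix <- tidyr::unnest(select(kept, "line_id", "pixels"), "pixels")
  utils::write.csv(as.data.frame(pix), paths$pixels, row.names = FALSE)
  write_json_file(list(theta_c_deg = theta_c$theta_c_deg,
                       spectral_contrast = theta_c$contrast,
                       low_confidence = theta_c$low_confidence,
                       parameters = rc,
                       summary = as.list(stats_$summary)),
                  paths$report)
  write_manifest(out_dir, "ridges", config, image_path,
                 unlist(paths, use.names = FALSE))
  invisible(paths)
}

#' @rdname pipeline-runners
#' @export
run_strain <- function(points_path, experiment_path,
                       config = default_config(), out_dir = ".",
                       control_points_path = NULL, control_experiment_path = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp_ <- read_experiment(points_path, experiment_path)
  tbl <- run_strain_experiment(exp_, theta_c_deg = config$strain$theta_c_deg)
  paths <- list(strain = file.path(out_dir, "strain.csv"))
  utils::write.csv(as.data.frame(tbl), paths$strain, row.names = FALSE)
  inputs <- c(points_path, experiment_path)
  if (!is.null(control_points_path)) {
    ctrl <- read_experiment(control_points_path, control_experiment_path)
    ctbl <- run_strain_experiment(ctrl, theta_c_deg = config$strain$theta_c_deg)
    stats_tbl <- compare_strain_groups(tbl, ctbl)
    paths$stats <- file.path(out_dir, "stats.json")
    write_json_file(purrr::transpose(as.list(stats_tbl)) |>
                      stats::setNames(stats_tbl$test), paths$stats)
    inputs <- c(inputs, control_points_path, control_experiment_path)
  }
  write_manifest(out_dir, "strain", config, inputs,
                 unlist(paths, use.names = FALSE))
  invisible(paths)
}
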