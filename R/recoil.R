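#' Simulate a laser-ablation recoil experiment
#'
#' Emulates tracking of photoreceptor profile centroids around a laser-ablated
#' glial cell. Cone sites of the lattice outside the ablation hole are the
#' tracked points; at each post-ablation time the tissue has relaxed toward a
#' full affine deformation `M = R(rotation) diag(lambda_x, lambda_y)` applied
#' about the hole center, following an exponential saturation
#' `f(t) = (1 - exp(-t/tau)) / (1 - exp(-t_max/tau))` (so the final timepoint
#' carries the full deformation), plus i.i.d. Gaussian positional noise.
#' CONTROL experiments apply the identity deformation plus noise.
#'
#' With the default lattice orientation (columns along +y), `lambda_y` is the
#' stretch parallel to the columns and `lambda_x` perpendicular to them.
#'
#' @param lattice a `mosaic_lattice` supplying the tracked cell positions.
#' @param hole_center 2-vector (um); defaults to the lattice centroid.
#' @param hole_radius radius (um) of the ablation hole; sites inside are
#'   excluded from tracking.
#' @param strain_true c(lambda_x, lambda_y) true principal stretches (> 0).
#' @param rotation_deg rigid rotation of the deformation (degrees, ccw).
#' @param translation 2-vector (um) rigid translation at full relaxation.
#' @param times_min strictly increasing post-ablation times (minutes).
#' @param noise_sd positional tracking noise sd (um).
#' @param group `"ABLATION"` or `"CONTROL"`.
#' @param seed integer seed for the noise.
#' @param tau_min saturation time constant (minutes).
#' @return An object of class `ablation_experiment`: list with `points_pre`
#'   (tibble `point_id`, `x_um`, `y_um`), `points_post` (list of tibbles, one
#'   per time), `times_min`, `group`, `hole` and `truth` (`M_true`, `b_true`,
#'   `noise_sd`).
#' @export
simulate_ablation_recoil <- function(lattice,
                                     hole_center = NULL,
                                     hole_radius = 3,
                                     strain_true = c(1, 1.2),
                                     rotation_deg = 0,
                                     translation = c(0, 0),
                                     times_min = c(5, 15, 30, 60),
                                     noise_sd = 0,
                                     group = c("ABLATION", "CONTROL"),
                                     seed = 1L,
                                     tau_min = 20) {
  group <- match.arg(group)
  if (any(strain_true <= 0)) abort("Stretch ratios must be positive.")
  if (is.unsorted(times_min, strictly = TRUE)) abort("`times_min` must be strictly increasing.")
  cones <- lattice[lattice$subtype != "ROD", ]
  if (is.null(hole_center)) hole_center <- c(mean(cones$x_um), mean(cones$y_um))
  d <- sqrt((cones$x_um - hole_center[1])^2 + (cones$y_um - hole_center[2])^2)
  keep <- cones[d > hole_radius, ]
  if (!nrow(keep)) abort("No tracked points outside the ablation hole.")

  pre <- tibble(point_id = seq_len(nrow(keep)), x_um = keep$x_um, y_um = keep$y_um)
  phi <- rotation_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  M_full <- R %*% diag(strain_true)
  t_max <- max(times_min)
  f_t <- (1 - exp(-times_min / tau_min)) / (1 - exp(-t_max / tau_min))

  p0 <- cbind(pre$x_um - hole_center[1], pre$y_um - hole_center[2])
  post <- with_local_seed(seed, lapply(seq_along(times_min), function(k) {
    if (group == "CONTROL") {
      Mk <- diag(2); bk <- c(0, 0)
    } else {
      Mk <- diag(2) + f_t[k] * (M_full - diag(2))
      bk <- f_t[k] * translation
    }
    p <- p0 %*% t(Mk)
    p[, 1] <- p[, 1] + hole_center[1] + bk[1]
    p[, 2] <- p[, 2] + hole_center[2] + bk[2]
    if (noise_sd > 0) p <- p + matrix(rnorm(length(p), sd = noise_sd), ncol = 2)
    tibble(point_id = pre$point_id, x_um = p[, 1], y_um = p[, 2])
  }))

  M_true <- if (group == "CONTROL") diag(2) else M_full
  b_true <- if (group == "CONTROL") c(0, 0) else
    as.numeric(hole_center - M_full %*% hole_center + translation)
  structure(list(points_pre = pre, points_post = post, times_min = times_min,
                 group = group,
                 hole = list(center = hole_center, radius = hole_radius),
                 truth = list(M_true = M_true, b_true = b_true,
                              noise_sd = noise_sd, tau_min = tau_min)),
            class = "ablation_experiment")
}

#' @export
print.ablation_experiment <- function(x, ...) {
  cat(sprintf("ablation_experiment [%s]: %d tracked points, times %s min\n",
              x$group, nrow(x$points_pre), paste(x$times_min, collapse = ", ")))
  invisible(x)
}

#' Tracked centroids of an ablation experiment as one tidy table
#'
#' @param x an `ablation_experiment`.
#' @param ... unused.
#' @return Tibble with `point_id`, `time_min` (0 = pre-ablation), `x_um`,
#'   `y_um`.
#' @export
as_tibble.ablation_experiment <- function(x, ...) {
  bind_rows(
    mutate(x$points_pre, time_min = 0),
    purrr::map2_dfr(x$points_post, x$times_min,
                    function(p, t) mutate(p, time_min = t))
  ) |>
    select("point_id", "time_min", "x_um", "y_um") |>
    arrange(.data$time_min, .data$point_id)
}
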