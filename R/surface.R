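## OLM surface reconstruction and selective projection.

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map: %d x %d px, z in [%.2f, %.2f] um, %.0f%% valid\n",
              nrow(x$z_um), ncol(x$z_um), min(x$z_um), max(x$z_um),
              100 * mean(x$valid)))
  invisible(x)
}

# Gaussian kernel (sum 1) of width sigma (in samples).
gauss_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- -radius:radius
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# Gaussian blur of a matrix via EBImage::filter2 with zero padding; used in
# normalized-convolution form so constants survive image borders exactly.
blur2_zero <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  radius <- min(ceiling(3 * sigma_px), floor((min(dim(img)) - 1) / 2))
  k1 <- gauss_kernel_1d(sigma_px, radius = max(radius, 1L))
  EBImage::filter2(img, outer(k1, k1), boundary = 0)
}

#' Reconstruct the OLM surface from a z-stack
#'
#' Estimates the depth z(x, y) of the bright apical surface (the outer
#' limiting membrane) in a junction-label channel. Each pixel's z-profile is
#' smoothed with a Gaussian kernel in z and the surface depth taken at the
#' smoothed maximum, refined to sub-voxel precision by parabolic
#' interpolation. A confidence map (peak prominence, normalized to [0, 1])
#' flags low-signal pixels; those, and any manually masked pixels (e.g. glial
#' radial fibers), are filled by normalized-convolution interpolation from
#' their confident neighbors, after which the height field is smoothed
#' laterally.
#'
#' @param stack an [image_stack].
#' @param channel channel name carrying the surface label (e.g. `"zo1"`).
#' @param z_kernel_sigma_um Gaussian width of the z-smoothing (um).
#' @param xy_smooth_sigma_um lateral smoothing of the height field (um).
#' @param mask optional logical matrix (ny x nx); `TRUE` pixels are treated
#'   as low-confidence and interpolated.
#' @param confidence_floor pixels with normalized prominence below this are
#'   interpolated rather than trusted.
#' @param method `"argmax"` (default; depth of the smoothed peak) or
#'   `"centroid"` (intensity-weighted mean depth).
#' @return Object of class `surface_map`: list with `z_um`, `confidence`,
#'   `valid` matrices, grid metadata, and a `tilt_plane` slot (`NULL` until
#'   [estimate_tilt()] is run).
#' @export
reconstruct_olm_surface <- function(stack, channel,
                                    z_kernel_sigma_um = 1.8,
                                    xy_smooth_sigma_um = 0.6,
                                    mask = NULL,
                                    confidence_floor = 0.1,
                                    method = c("argmax", "centroid")) {
  method <- match.arg(method)
  if (!channel %in% names(stack$channels)) abort(sprintf("No channel '%s' in stack.", channel))
  if (z_kernel_sigma_um <= 0) abort("`z_kernel_sigma_um` must be positive.")
  arr <- stack$channels[[channel]]
  if (all(arr == 0)) abort("Channel is identically zero: no surface evidence.")
  d <- dim(arr); nz <- d[1]; ny <- d[2]; nx <- d[3]
  dz <- stack$voxel_size_um[1]
  px <- stack$voxel_size_um[3]

  ## Gaussian smoothing of every z-profile (row-normalized so edge slices
  ## keep unit weight).
  sig_z <- z_kernel_sigma_um / dz
  K <- outer(seq_len(nz), seq_len(nz), function(a, b) exp(-0.5 * ((a - b) / sig_z)^2))
  K <- K / rowSums(K)
  S <- K %*% matrix(arr, nz, ny * nx)

  St <- t(S)
  peak_idx <- max.col(St, ties.method = "first")
  n_px <- ny * nx
  peak_val <- St[cbind(seq_len(n_px), peak_idx)]

  if (method == "centroid") {
    zs <- (seq_len(nz) - 0.5) * dz
    zf_um <- as.vector((zs %*% S) / colSums(S))
  } else {
    lo <- pmax(peak_idx - 1L, 1L); hi <- pmin(peak_idx + 1L, nz)
    y0 <- St[cbind(seq_len(n_px), lo)]
    y1 <- peak_val
    y2 <- St[cbind(seq_len(n_px), hi)]
    # log-parabola: exact sub-voxel peak for a Gaussian axial profile (which
    # the rendered signal remains after Gaussian z-smoothing), unbiased even
    # when the profile is undersampled in z
    floor_v <- pmax(y1, .Machine$double.xmin) * 1e-12
    l0 <- log(pmax(y0, floor_v)); l1 <- log(pmax(y1, floor_v)); l2 <- log(pmax(y2, floor_v))
    denom <- l0 - 2 * l1 + l2
    delta <- ifelse(abs(denom) > .Machine$double.eps, 0.5 * (l0 - l2) / denom, 0)
    delta[peak_idx == 1L | peak_idx == nz] <- 0
    delta <- pmax(pmin(delta, 0.5), -0.5)
    zf_um <- (peak_idx + delta - 0.5) * dz
  }
  z_um <- matrix(zf_um, ny, nx)

  prom <- peak_val - St[cbind(seq_len(n_px), max.col(-St, ties.method = "first"))]
  conf <- matrix(prom / max(prom), ny, nx)
  valid <- conf >= confidence_floor
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(valid))) abort("Mask shape must match the stack (y, x) extent.")
    conf[mask] <- 0
    valid <- valid & !mask
  }
  if (sum(valid) < 3) abort("Too few confident pixels to reconstruct a surface.")

  ## fill unreliable pixels from confident neighbors (normalized convolution,
  ## widening the kernel until every pixel is covered)
  w <- conf * valid
  if (any(!valid)) {
    sig_f <- max(3, 2 * xy_smooth_sigma_um / px)
    repeat {
      num <- blur2_zero(z_um * w, sig_f)
      den <- blur2_zero(w, sig_f)
      if (all(den[!valid] > 1e-12) || sig_f > 4 * max(ny, nx)) break
      sig_f <- 2 * sig_f
    }
    z_um[!valid] <- num[!valid] / den[!valid]
  }

  ## lateral smoothing (normalized so borders are unbiased for constants)
  sig_xy <- xy_smooth_sigma_um / px
  if (sig_xy > 0) {
    ones <- matrix(1, ny, nx)
    z_um <- blur2_zero(z_um, sig_xy) / blur2_zero(ones, sig_xy)
  }

  structure(list(z_um = z_um, confidence = conf, valid = valid,
                 voxel_size_um = stack$voxel_size_um,
                 pixel_size_um = px, origin_um = stack$origin_um,
                 smooth_sigma_px = sig_xy, tilt_plane = NULL),
            class = "surface_map")
}

#' Selectively project a channel at the OLM surface
#'
#' Reduces, for every (x, y) pixel, the intensities of the slices whose depth
#' lies within `band_halfwidth_um` of the reconstructed surface. When no
#' slice center falls inside the band, the slice nearest to the surface is
#' used.
#'
#' @param stack an [image_stack].
#' @param channel channel name to project.
#' @param surface a `surface_map` for the same stack geometry.
#' @param band_halfwidth_um half-width of the projection band (um, >= 0).
#' @param reducer `"max"` or `"mean"`.
#' @return A [projection2d].
#' @export
project_at_surface <- function(stack, channel, surface, band_halfwidth_um = 2,
                               reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  if (band_halfwidth_um < 0) abort("`band_halfwidth_um` must be >= 0.")
  if (!channel %in% names(stack$channels)) abort(sprintf("No channel '%s' in stack.", channel))
  arr <- stack$channels[[channel]]
  d <- dim(arr)
  if (!identical(d[2:3], dim(surface$z_um))) {
    abort("Surface and stack (y, x) shapes differ.", class = "mosaicmech_geometry_error")
  }
  nz <- d[1]; dz <- stack$voxel_size_um[1]
  z <- surface$z_um
  acc <- matrix(if (reducer == "max") -Inf else 0, d[2], d[3])
  cnt <- matrix(0, d[2], d[3])
  for (k in seq_len(nz)) {
    inband <- abs((k - 0.5) * dz - z) <= band_halfwidth_um
    sl <- arr[k, , ]
    if (reducer == "max") {
      acc[inband] <- pmax(acc[inband], sl[inband])
    } else {
      acc[inband] <- acc[inband] + sl[inband]
    }
    cnt <- cnt + inband
  }
  none <- cnt == 0
  if (any(none)) {
    nearest <- pmin(pmax(round(z / dz + 0.5), 1), nz)
    idx <- which(none)
    acc[idx] <- arr[cbind(nearest[idx],
                          ((idx - 1) %% d[2]) + 1,
                          ((idx - 1) %/% d[2]) + 1)]
    cnt[none] <- 1
  }
  img <- if (reducer == "mean") acc / cnt else acc
  projection2d(img, channel, stack$voxel_size_um[3], stack$origin_um,
               band_halfwidth_um = band_halfwidth_um)
}

#' Estimate the OLM tilt plane
#'
#' Confidence-weighted least-squares plane through the reconstructed height
#' field, used to correct for sample inclination. A border of
#' `trim_border_px` pixels (default: the lateral smoothing support) is
#' excluded from the fit because smoothing biases the height field there.
#'
#' @param surface a `surface_map`.
#' @param trim_border_px pixels to drop along each image edge.
#' @return `tilt_plane` list: `normal` (unit 3-vector with positive z
#'   component), `offset_um` (`normal . p` for points p on the plane),
#'   `tilt_deg` (angle between the normal and +z), `slope` (dz/dx, dz/dy).
#' @export
estimate_tilt <- function(surface, trim_border_px = NULL) {
  z <- surface$z_um
  ny <- nrow(z); nx <- ncol(z)
  trim <- trim_border_px %||% ceiling(2 * (surface$smooth_sigma_px %||% 0))
  keep_r <- seq_len(ny) > trim & seq_len(ny) <= ny - trim
  keep_c <- seq_len(nx) > trim & seq_len(nx) <= nx - trim
  sel <- outer(keep_r, keep_c) & surface$valid
  if (sum(sel) < 3) abort("Too few valid pixels to fit a tilt plane.",
                          class = "mosaicmech_geometry_error")
  g <- pixel_grid(ny, nx, surface$pixel_size_um, surface$origin_um)
  w <- surface$confidence[sel]
  X <- cbind(g$x[sel], g$y[sel], 1)
  fit <- stats::lm.wfit(X, z[sel], w)
  ab <- fit$coefficients
  if (any(!is.finite(ab))) abort("Degenerate geometry: tilt plane is underdetermined.",
                                 class = "mosaicmech_geometry_error")
  n <- c(-ab[1], -ab[2], 1)
  N <- sqrt(sum(n^2))
  n <- n / N
  list(normal = unname(n), offset_um = unname(ab[3] / N),
       tilt_deg = acos(min(1, n[3])) * 180 / pi,
       slope = unname(ab[1:2]))
}
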