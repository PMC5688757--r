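## Oriented glial-band detection: steerable Gaussian-derivative ridge filter,
## FFT column-direction estimate, ridge refinement, and the angular/length
## filtering rules.

# n-th derivative of a Gaussian of width sigma, sampled on -radius:radius,
# via the probabilists' Hermite recurrence. The order-0 kernel sums to 1;
# higher orders are mean-subtracted so their truncated samples integrate to
# exactly zero (a constant image then gives an exactly zero response).
gauss_deriv_1d <- function(n, sigma, radius = ceiling(4 * sigma)) {
  x <- -radius:radius
  g <- exp(-0.5 * (x / sigma)^2)
  g <- g / sum(g)
  if (n == 0) return(g)
  t <- x / sigma
  He <- list(rep(1, length(x)), t)
  if (n >= 2) for (k in 2:n) He[[k + 1]] <- t * He[[k]] - (k - 1) * He[[k - 1]]
  k <- (-1 / sigma)^n * He[[n + 1]] * g
  k - mean(k)
}

# steered order-n directional-derivative responses: returns a function of the
# derivative direction phi given the n + 1 separable basis convolutions
steer_basis <- function(image, n, sigma, radius) {
  deriv <- lapply(0:n, gauss_deriv_1d, sigma = sigma, radius = radius)
  B <- vapply(0:n, function(k) {
    kern <- outer(deriv[[k + 1]], deriv[[n - k + 1]])  # d^n/dx^(n-k) dy^k
    as.vector(EBImage::filter2(image, kern, boundary = "replicate"))
  }, numeric(length(image)))
  ks <- 0:n
  binom <- choose(n, ks)
  function(phi) drop(B %*% (binom * cos(phi)^(n - ks) * sin(phi)^ks))
}

#' Steerable Gaussian-derivative ridge filter
#'
#' For every pixel, finds the orientation maximizing the response of an
#' even-order steerable Gaussian-derivative ridge template, and returns that
#' maximal response (ridge-likeness score) together with the optimal ridge
#' orientation, defined modulo 180 degrees. Directional derivatives are
#' steered analytically from their separable basis convolutions, so the
#' angular search is exact up to the `angle_step_deg` sampling. Scores are
#' defined up to a positive scale; downstream thresholds are quantile-based.
#'
#' For `order >= 4` the template combines the order-N and second directional
#' derivatives across the candidate ridge,
#' `sigma^N D^N - alpha sigma^2 D^2`, in the tradition of optimized steerable
#' ridge detectors: the second-derivative term (weight
#' `sidelobe_suppression`, default 3) cancels the positive secondary lobes of
#' the bare high-order derivative, which would otherwise detect phantom
#' ridges flanking a genuine one. `order = 2` is the bare (negated) second
#' directional derivative.
#'
#' The template scale is `sigma = width_px / (2 sqrt(2))`, which places the
#' template's ridge-response FWHM near `width_px` (default 8 px, the typical
#' thickness of inter-column glial bands).
#'
#' @param image numeric matrix or [projection2d].
#' @param order even filter order >= 2 (default 4).
#' @param width_px nominal ridge width in pixels (default 8).
#' @param angle_step_deg angular sampling of the orientation search.
#' @param sidelobe_suppression weight of the second-derivative term for
#'   `order >= 4`.
#' @return Object of class `ridge_field`: list with `score` and `angle_deg`
#'   matrices, `order`, `width_px`, `sigma_px`.
#' @export
steerable_ridge_filter <- function(image, order = 4, width_px = 8,
                                   angle_step_deg = 1, sidelobe_suppression = 3) {
  proj <- NULL
  if (inherits(image, "projection2d")) { proj <- image; image <- image$image }
  if (order < 2 || order %% 2 != 0) abort("`order` must be even and >= 2.")
  if (width_px < 1) abort("`width_px` must be >= 1.")
  sigma <- width_px / (2 * sqrt(2))
  radius <- ceiling(4 * sigma)
  if (any(dim(image) < 2 * radius + 1)) {
    abort("Image smaller than the filter kernel support.", class = "mosaicmech_sizing_error")
  }
  ny <- nrow(image); nx <- ncol(image)

  d2 <- steer_basis(image, 2L, sigma, radius)
  dN <- if (order > 2) steer_basis(image, as.integer(order), sigma, radius) else NULL
  # bright-ridge response sign of the bare order-N derivative at the center
  sgn <- if (order %% 4 == 0) 1 else -1
  respond <- function(phi) {
    if (order == 2) return(-sigma^2 * d2(phi))
    sgn * sigma^order * dN(phi) - sidelobe_suppression * sigma^2 * d2(phi)
  }

  phis <- seq(0, 180 - angle_step_deg, by = angle_step_deg) * pi / 180
  score <- rep(-Inf, ny * nx)
  best_phi <- numeric(ny * nx)
  for (phi in phis) {
    resp <- respond(phi)
    better <- resp > score
    score[better] <- resp[better]
    best_phi[better] <- phi
  }
  # the derivative direction phi is across the ridge; ridge angle = phi + 90
  angle <- (best_phi * 180 / pi + 90) %% 180
  structure(list(score = matrix(score, ny, nx),
                 angle_deg = matrix(angle, ny, nx),
                 order = order, width_px = width_px, sigma_px = sigma,
                 pixel_size_um = proj$pixel_size_um %||% NA_real_,
                 origin_um = proj$origin_um %||% c(0, 0)),
            class = "ridge_field")
}

#' @export
print.ridge_field <- function(x, ...) {
  cat(sprintf("ridge_field: order %d, width %d px, %d x %d px, score range [%.3g, %.3g]\n",
              x$order, x$width_px, nrow(x$score), ncol(x$score),
              min(x$score), max(x$score)))
  invisible(x)
}

# 8-connected components of a logical matrix, via the pixel adjacency graph.
label8 <- function(keep) {
  idx <- which(keep)
  if (!length(idx)) return(list(labels = integer(0), idx = idx))
  ny <- nrow(keep)
  nx <- ncol(keep)
  r <- ((idx - 1L) %% ny) + 1L
  c <- ((idx - 1L) %/% ny) + 1L
  id_of <- matrix(0L, ny, nx); id_of[idx] <- seq_along(idx)
  edges <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    ok[ok] <- keep[cbind(r2[ok], c2[ok])]
    if (any(ok)) edges[[length(edges) + 1L]] <-
        cbind(seq_along(idx)[ok], id_of[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::graph_from_edgelist(if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0, 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  list(labels = as.integer(comp), idx = idx, row = r, col = c)
}

shift_mask <- function(m, dr, dc, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  rs <- max(1, 1 + dr):min(ny, ny + dr); cs <- max(1, 1 + dc):min(nx, nx + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen morphological thinning of a binary mask to a unit-width,
# 8-connected skeleton (so ridge linking sees true junctions only).
thin_mask <- function(mask) {
  m <- mask * 1
  # neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      P <- lapply(offs, function(o) shift_mask(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (P[[i]] == 0) & (P[[if (i == 8) 1 else i + 1]] == 1)
      }))
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      if (sub == 0) {
        cond <- cond & (P[[1]] * P[[3]] * P[[5]] == 0) & (P[[3]] * P[[5]] * P[[7]] == 0)
      } else {
        cond <- cond & (P[[1]] * P[[3]] * P[[7]] == 0) & (P[[1]] * P[[5]] * P[[7]] == 0)
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# crossing number per pixel: 0 -> 1 transitions around the 8-neighborhood
# (1 = line end, 2 = interior line pixel, >= 3 = branch point)
crossing_number <- function(mask) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  P <- lapply(offs, function(o) shift_mask(mask * 1, o[1], o[2]))
  Reduce(`+`, lapply(1:8, function(i) {
    (P[[i]] == 0) & (P[[if (i == 8) 1 else i + 1]] == 1)
  }))
}

# Canny-style non-maximum suppression across the local ridge direction:
# keeps only pixels whose score is a local maximum along the direction
# perpendicular to their ridge orientation, thinning thick responses to
# one-pixel centerlines.
nms_across_ridge <- function(score, angle_deg) {
  ny <- nrow(score); nx <- ncol(score)
  perp <- (angle_deg + 90) %% 180
  sector <- (round(perp / 45) %% 4) + 1  # 1: x, 2: diag, 3: y, 4: anti-diag
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # (drow, dcol)
  shift_score <- function(dr, dc) {
    out <- matrix(-Inf, ny, nx)
    rs <- max(1, 1 + dr):min(ny, ny + dr); cs <- max(1, 1 + dc):min(nx, nx + dc)
    out[rs, cs] <- score[rs - dr, cs - dc]
    out
  }
  keep <- matrix(FALSE, ny, nx)
  for (s in 1:4) {
    o <- offs[[s]]
    ok <- score >= shift_score(o[1], o[2]) & score >= shift_score(-o[1], -o[2])
    keep <- keep | (sector == s & ok)
  }
  keep
}

#' Refine a ridge field into linked ridge lines
#'
#' Thins the score map to one-pixel ridge centerlines by non-maximum
#' suppression across the local ridge direction, suppresses pixels with low
#' ridge-likeness (below the `score_quantile` quantile of the score map) and
#' isolated surviving pixels (fewer than `min_neighbors` 8-connected
#' survivors), then links the remaining pixels into connected ridge lines,
#' splitting at junction pixels (more than two surviving neighbors). Each
#' line carries its pixel path ordered along the line's principal axis, its
#' circular mean orientation and its length in pixels.
#'
#' Pixels within the filter's kernel support of the image border carry
#' boundary-extension artifacts and are excluded (`border_px`, defaulting to
#' the kernel radius).
#'
#' @param field a `ridge_field`.
#' @param score_quantile quantile (0, 1) of the score map used as threshold.
#' @param min_neighbors minimum surviving 8-neighbors for a pixel to be kept.
#' @param border_px border exclusion band (pixels).
#' @return Tibble of class `ridge_lines`: `line_id`, `length_px`,
#'   `mean_angle_deg`, `mean_score`, and `pixels` (list column of tibbles
#'   with `row`, `col`). An empty tibble when nothing survives.
#' @export
refine_ridges <- function(field, score_quantile = 0.8, min_neighbors = 1,
                          border_px = NULL) {
  if (score_quantile <= 0 || score_quantile >= 1) abort("`score_quantile` must be in (0, 1).")
  thr <- quantile(field$score, score_quantile, names = FALSE)
  keep <- field$score >= thr & field$score > 0 &
    nms_across_ridge(field$score, field$angle_deg)
  b <- border_px %||% ceiling(4 * (field$sigma_px %||% 0))
  if (b > 0) {
    ny <- nrow(keep); nx <- ncol(keep)
    bb <- min(b, floor((min(ny, nx) - 1) / 2))
    keep[c(seq_len(bb), ny - seq_len(bb) + 1L), ] <- FALSE
    keep[, c(seq_len(bb), nx - seq_len(bb) + 1L)] <- FALSE
  }
  kernel8 <- matrix(1, 3, 3); kernel8[2, 2] <- 0
  nb <- round(EBImage::filter2(keep * 1, kernel8, boundary = 0))
  keep <- keep & nb >= min_neighbors
  # thin to a unit-width skeleton, then split at true junctions: pixels whose
  # 8-neighborhood crossing number (0 -> 1 transitions around the pixel) is
  # >= 3, i.e. genuine branch points rather than staircase corners
  keep <- thin_mask(keep)
  keep_line <- keep & crossing_number(keep) <= 2
  lab <- label8(keep_line)
  empty <- tibble(line_id = integer(), length_px = integer(),
                  mean_angle_deg = numeric(), mean_score = numeric(),
                  pixels = list())
  if (!length(lab$idx)) {
    return(structure(empty, class = c("ridge_lines", class(empty)), field = field))
  }
  df <- tibble(comp = lab$labels, row = lab$row, col = lab$col,
               score = field$score[lab$idx], angle = field$angle_deg[lab$idx])
  lines <- df |>
    group_by(.data$comp) |>
    group_map(function(g, key) {
      # order pixels along the principal axis of the component
      rc <- cbind(g$col, g$row)
      rc_c <- sweep(rc, 2, colMeans(rc))
      dir <- svd(rc_c, nu = 0, nv = 1)$v[, 1]
      ord <- order(rc_c %*% dir)
      ang2 <- g$angle * pi / 90  # doubled angles for 180-periodic mean
      tibble(length_px = nrow(g),
             mean_angle_deg = (atan2(mean(sin(ang2)), mean(cos(ang2))) * 90 / pi) %% 180,
             mean_score = mean(g$score),
             pixels = list(tibble(row = g$row[ord], col = g$col[ord])))
    }) |>
    bind_rows() |>
    mutate(line_id = dplyr::row_number()) |>
    select("line_id", "length_px", "mean_angle_deg", "mean_score", "pixels")
  structure(lines, class = c("ridge_lines", class(lines)), field = field)
}

#' Estimate the cone column direction from an image power spectrum
#'
#' Computes the 2D power spectrum of the (mean-subtracted) image with the DC
#' component and a small low-frequency disc removed, locates the dominant
#' spectral direction (refined by a local power-weighted centroid), and
#' returns the column direction: the direction with the largest Fourier
#' amplitude is perpendicular to the columns, so
#' `theta_c = peak direction + 90` (mod 180). A near-isotropic spectrum
#' (peak-to-median power below `contrast_floor`) is flagged low-confidence.
#'
#' @param image numeric matrix or [projection2d] with non-zero variance.
#' @param exclude_radius low-frequency exclusion radius, in frequency bins of
#'   the smaller image dimension.
#' @param contrast_floor minimum peak/median power ratio for a confident
#'   estimate.
#' @return Object of class `column_direction`: list with `theta_c_deg`,
#'   `spectral_peak_magnitude`, `contrast`, `low_confidence`.
#' @export
estimate_column_direction <- function(image, exclude_radius = 2, contrast_floor = 50) {
  if (inherits(image, "projection2d")) image <- image$image
  if (stats::sd(image) <= .Machine$double.eps * max(abs(image), 1)) {
    abort("Flat image: no anisotropy to estimate a direction from.",
          class = "mosaicmech_geometry_error")
  }
  ny <- nrow(image); nx <- ncol(image)
  P <- Mod(stats::fft(image - mean(image)))^2
  ky <- ifelse(0:(ny - 1) > ny / 2, 0:(ny - 1) - ny, 0:(ny - 1))
  kx <- ifelse(0:(nx - 1) > nx / 2, 0:(nx - 1) - nx, 0:(nx - 1))
  fy <- matrix(ky / ny, ny, nx)
  fx <- matrix(kx / nx, ny, nx, byrow = TRUE)
  fr <- sqrt(fx^2 + fy^2)
  usable <- fr > exclude_radius / min(ny, nx) &
    (fx > 0 | (abs(fx) < 1e-12 & fy > 0))   # one half-plane (conjugate symmetry)
  if (!any(usable)) abort("Image too small for spectral direction estimation.")
  Pu <- ifelse(usable, P, NA_real_)
  pk <- arrayInd(which.max(ifelse(usable, P, -Inf)), dim(P))
  # power-weighted centroid over the 3x3 neighborhood of the peak (wrapped)
  ri <- ((pk[1] - 2L):(pk[1])) %% ny + 1L
  ci <- ((pk[2] - 2L):(pk[2])) %% nx + 1L
  wgt <- P[ri, ci]
  fxc <- sum(fx[ri, ci] * wgt) / sum(wgt)
  fyc <- sum(fy[ri, ci] * wgt) / sum(wgt)
  alpha <- (atan2(fyc, fxc) * 180 / pi) %% 180
  med <- median(Pu, na.rm = TRUE)
  contrast <- if (med > 0) max(P[usable]) / med else Inf
  structure(list(theta_c_deg = (alpha + 90) %% 180,
                 spectral_peak_magnitude = sqrt(max(P[usable])),
                 contrast = contrast,
                 low_confidence = contrast < contrast_floor),
            class = "column_direction")
}

#' @export
print.column_direction <- function(x, ...) {
  cat(sprintf("column_direction: theta_c = %.2f deg (contrast %.1f%s)\n",
              x$theta_c_deg, x$contrast,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Filter ridge lines by orientation and length
#'
#' Keeps lines whose 180-degree-periodic angular deviation from the column
#' direction is at most `max_dev_deg` (lines deviating more are spurious
#' within-column lamellae) and whose length is at least `min_length_px`.
#'
#' @param lines a `ridge_lines` tibble.
#' @param theta_c column direction (degrees or `column_direction`).
#' @param max_dev_deg maximum angular deviation (degrees; default 30).
#' @param min_length_px minimum line length in pixels (default 20).
#' @return The filtered `ridge_lines` tibble with an added
#'   `deviation_deg` column.
#' @export
filter_ridges <- function(lines, theta_c, max_dev_deg = 30, min_length_px = 20) {
  if (inherits(theta_c, "column_direction")) theta_c <- theta_c$theta_c_deg
  out <- lines |>
    mutate(deviation_deg = circ_dist180(.data$mean_angle_deg, theta_c)) |>
    filter(.data$deviation_deg <= max_dev_deg, .data$length_px >= min_length_px)
  structure(out, class = class(lines), field = attr(lines, "field"))
}

#' Summary statistics of a set of ridge lines
#'
#' @param lines a `ridge_lines` tibble.
#' @param theta_c column direction (degrees or `column_direction`).
#' @param hist_breaks_deg orientation histogram bin width (degrees).
#' @return List of class `ridge_summary` with `summary` (one-row tibble:
#'   `n_lines`, `total_length_px`, `mean_abs_deviation_deg`) and `histogram`
#'   (tibble of length-weighted orientation bins).
#' @export
ridge_statistics <- function(lines, theta_c, hist_breaks_deg = 10) {
  if (inherits(theta_c, "column_direction")) theta_c <- theta_c$theta_c_deg
  dev <- circ_dist180(lines$mean_angle_deg, theta_c)
  breaks <- seq(0, 180, by = hist_breaks_deg)
  bin <- cut(lines$mean_angle_deg %% 180, breaks, right = FALSE, include.lowest = TRUE)
  wlen <- vapply(split(lines$length_px, bin), sum, numeric(1))
  hist <- tibble(bin_start_deg = breaks[-length(breaks)],
                 bin_end_deg = breaks[-1],
                 total_length_px = as.numeric(wlen))
  structure(list(
    summary = tibble(n_lines = nrow(lines),
                     total_length_px = sum(lines$length_px),
                     mean_abs_deviation_deg = if (nrow(lines)) mean(dev) else NA_real_),
    histogram = hist), class = "ridge_summary")
}

#' @export
print.ridge_summary <- function(x, ...) {
  print(x$summary, ...)
  invisible(x)
}
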