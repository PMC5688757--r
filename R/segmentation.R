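## Seeded segmentation of apical cell profiles from a boundary-channel
## projection, per-profile reporter intensity, 2-means classification, and
## the positive:negative ratio.

seeds_to_pixels <- function(seeds, proj) {
  s <- as_point_matrix(seeds)
  px <- proj$pixel_size_um
  col <- pmin(pmax(ceiling((s[, 1] - proj$origin_um[1]) / px), 1L), ncol(proj$image))
  row <- pmin(pmax(ceiling((s[, 2] - proj$origin_um[2]) / px), 1L), nrow(proj$image))
  cbind(row = row, col = col)
}

#' Segment cell profiles from a boundary image with placed seeds
#'
#' Performs seeded watershed-style segmentation of a junction-label
#' projection (bright boundaries, dark cell interiors): starting from one
#' seed per cell, regions grow over the boundary-intensity landscape
#' (EBImage's seeded propagation) until they meet at the bright walls.
#' Pixels under the optional exclusion mask (e.g. manually outlined
#' irregular glial profiles) take no part in the segmentation and are
#' reported as a single EXCLUDED profile; seeds falling inside the mask are
#' dropped with a warning.
#'
#' @param boundary a [projection2d] of the boundary channel.
#' @param seeds seed positions in um (matrix or data frame with
#'   `x_um`, `y_um`), one per expected cell, on pairwise distinct pixels.
#' @param exclusion_mask optional logical matrix (`TRUE` = excluded).
#' @return Tibble of class `cell_profiles`: `profile_id`, `x_um`, `y_um`
#'   (centroid), `area_um2`, `mean_intensity` (`NA` until
#'   [measure_intensity()]), `label` (`NA`, or `"EXCLUDED"`). The label
#'   image is attached as attribute `label_image`; dropped-seed count as
#'   `n_dropped_seeds`.
#' @export
segment_profiles <- function(boundary, seeds, exclusion_mask = NULL) {
  img <- boundary$image
  sp <- seeds_to_pixels(seeds, boundary)
  if (anyDuplicated(sp)) abort("Seeds must lie on pairwise distinct pixels.")
  n_dropped <- 0L
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(img))) abort("Exclusion mask shape mismatch.")
    on_excl <- exclusion_mask[sp]
    n_dropped <- sum(on_excl)
    if (n_dropped > 0) {
      warn(sprintf("%d seed(s) fell on excluded pixels and were dropped.", n_dropped))
      sp <- sp[!on_excl, , drop = FALSE]
    }
  }
  if (!nrow(sp)) abort("No usable seeds outside the exclusion mask.")

  seed_img <- matrix(0L, nrow(img), ncol(img))
  seed_img[sp] <- seq_len(nrow(sp))
  mask <- if (is.null(exclusion_mask)) NULL else !exclusion_mask
  lab <- EBImage::imageData(EBImage::propagate(img, seed_img, mask = mask, lambda = 1e-4))
  lab <- matrix(as.integer(round(lab)), nrow(img), ncol(img))

  px <- boundary$pixel_size_um
  g <- pixel_grid(nrow(img), ncol(img), px, boundary$origin_um)
  ids <- seq_len(nrow(sp))
  rows <- purrr::map_dfr(ids, function(i) {
    sel <- lab == i
    tibble(profile_id = i,
           x_um = mean(g$x[sel]), y_um = mean(g$y[sel]),
           area_um2 = sum(sel) * px^2,
           mean_intensity = NA_real_, label = NA_character_)
  })
  if (!is.null(exclusion_mask) && any(exclusion_mask)) {
    excl_id <- nrow(sp) + 1L
    lab[exclusion_mask] <- excl_id
    rows <- bind_rows(rows, tibble(
      profile_id = excl_id,
      x_um = mean(g$x[exclusion_mask]), y_um = mean(g$y[exclusion_mask]),
      area_um2 = sum(exclusion_mask) * px^2,
      mean_intensity = NA_real_, label = "EXCLUDED"))
  }
  structure(rows, class = c("cell_profiles", class(rows)),
            label_image = lab, n_dropped_seeds = n_dropped,
            pixel_size_um = px, origin_um = boundary$origin_um)
}

#' Measure mean reporter intensity per profile
#'
#' Fills `mean_intensity` with the mean of the reporter projection over each
#' profile's pixels; EXCLUDED profiles are left untouched.
#'
#' @param profiles a `cell_profiles` tibble from [segment_profiles()].
#' @param reporter a [projection2d] with the same geometry.
#' @return The `cell_profiles` tibble with `mean_intensity` filled.
#' @export
measure_intensity <- function(profiles, reporter) {
  lab <- attr(profiles, "label_image")
  if (!identical(dim(lab), dim(reporter$image))) abort("Reporter geometry mismatch.")
  for (i in seq_len(nrow(profiles))) {
    if (identical(profiles$label[i], "EXCLUDED")) next
    sel <- lab == profiles$profile_id[i]
    if (!any(sel)) abort(sprintf("Profile %d has an empty mask.", profiles$profile_id[i]))
    profiles$mean_intensity[i] <- mean(reporter$image[sel])
  }
  profiles
}

# Exact optimal two-cluster split of 1D values (minimum within-cluster sum of
# squares over all thresholds on the sorted values).
exact_two_means <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cq <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wss <- (cq[k] - cs[k]^2 / k) +
    ((cq[n] - cq[k]) - (cs[n] - cs[k])^2 / (n - k))
  kbest <- which.min(wss)
  hi <- logical(n); hi[ord[(kbest + 1):n]] <- TRUE
  hi  # TRUE = high-intensity cluster
}

#' Classify profiles as reporter-positive or -negative
#'
#' Two-cluster partition of the per-profile mean reporter intensities; the
#' cluster with the higher centroid is POSITIVE. The default solver is the
#' exact 1D two-cluster optimum (enumeration over thresholds on the sorted
#' intensities); `method = "kmeans"` uses [stats::kmeans()] with 10 restarts
#' under a fixed seed. Both give the globally optimal 1D partition on
#' well-separated data; the exact solver is deterministic by construction.
#'
#' @param profiles a measured `cell_profiles` tibble.
#' @param method `"exact"` (default) or `"kmeans"`.
#' @param seed seed for the k-means restarts.
#' @return The `cell_profiles` tibble with `label` set to `"POSITIVE"` /
#'   `"NEGATIVE"` (EXCLUDED rows untouched).
#' @export
classify_kmeans <- function(profiles, method = c("exact", "kmeans"), seed = 1L) {
  method <- match.arg(method)
  usable <- is.na(profiles$label) | profiles$label != "EXCLUDED"
  x <- profiles$mean_intensity[usable]
  if (sum(usable) < 2 || any(is.na(x))) abort("Need >= 2 measured, non-excluded profiles.")
  if (diff(range(x)) <= 0) abort("All intensities identical: unclassifiable.")
  hi <- if (method == "exact") {
    exact_two_means(x)
  } else {
    km <- with_local_seed(seed, stats::kmeans(x, centers = 2, nstart = 10))
    km$cluster == which.max(km$centers)
  }
  profiles$label[usable] <- ifelse(hi, "POSITIVE", "NEGATIVE")
  profiles
}

#' Ratio of positive to negative profiles
#'
#' @param profiles a classified `cell_profiles` tibble.
#' @return One-row tibble: `n_positive`, `n_negative`, `n_excluded`,
#'   `ratio_positive` (always 1) and `ratio_negative` (the x in 1:x).
#' @export
compute_ratio <- function(profiles) {
  n_pos <- sum(profiles$label == "POSITIVE", na.rm = TRUE)
  n_neg <- sum(profiles$label == "NEGATIVE", na.rm = TRUE)
  n_exc <- sum(profiles$label == "EXCLUDED", na.rm = TRUE)
  if (n_pos == 0) abort("No POSITIVE profiles: ratio undefined.")
  tibble(n_positive = n_pos, n_negative = n_neg, n_excluded = n_exc,
         ratio_positive = 1, ratio_negative = n_neg / n_pos)
}

#' Automatic seed proposal from a boundary image
#'
#' Convenience auto-seeder: local minima of the smoothed boundary image
#' (cell interiors are dark). Intended for exploration; analyses mirror the
#' manual-seed workflow and pass seeds explicitly.
#'
#' @param boundary a [projection2d].
#' @param smooth_sigma_px Gaussian presmoothing (pixels).
#' @param min_distance_px minimum spacing between seeds, via non-maximum
#'   suppression radius.
#' @return Tibble with `x_um`, `y_um`.
#' @export
auto_seed_profiles <- function(boundary, smooth_sigma_px = 3, min_distance_px = 5) {
  img <- blur2_zero(boundary$image, smooth_sigma_px)
  ny <- nrow(img); nx <- ncol(img)
  r <- min_distance_px
  # minimum filter by shifting
  mn <- img
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(Inf, ny, nx)
    rs <- max(1, 1 + dr):min(ny, ny + dr); cs <- max(1, 1 + dc):min(nx, nx + dc)
    sh[rs, cs] <- img[rs - dr, cs - dc]
    mn <- pmin(mn, sh)
  }
  sel <- which(img <= mn)
  rows <- ((sel - 1) %% ny) + 1; cols <- ((sel - 1) %/% ny) + 1
  px <- boundary$pixel_size_um
  tibble(x_um = boundary$origin_um[1] + (cols - 0.5) * px,
         y_um = boundary$origin_um[2] + (rows - 0.5) * px)
}
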