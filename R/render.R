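#' @importFrom stats rnorm quantile median
NULL

## ---- containers -----------------------------------------------------------

#' Construct a 3D multi-channel image stack
#'
#' Lightweight container for confocal-like data: one 3D array per channel with
#' dimensions (z, y, x), shared voxel spacing and a common spatial origin. The
#' center of slice `k` is at depth `(k - 0.5) * dz` and the center of pixel
#' `(i, j)` at `origin + (j - 0.5, i - 0.5) * pixel_size`.
#'
#' @param channels named list of 3D numeric arrays, identical dimensions.
#' @param voxel_size_um numeric (dz, dy, dx) in micrometers.
#' @param origin_um numeric (x0, y0) position of the image corner in um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um, origin_um = c(0, 0)) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1)))) {
    abort("All channels must share the same (z, y, x) dimensions.")
  }
  for (ch in channels) {
    if (!all(is.finite(ch)) || any(ch < 0)) abort("Channel intensities must be finite and >= 0.")
  }
  structure(list(channels = channels,
                 voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin_um)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s) [%s], %d z x %d y x %d x, voxel %.2f x %.2f x %.2f um\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Construct a 2D projection record
#'
#' @param image 2D numeric matrix (rows = y, cols = x).
#' @param source_channel name of the channel the image came from.
#' @param pixel_size_um pixel edge length (um).
#' @param origin_um (x0, y0) of the image corner (um).
#' @param band_halfwidth_um half-width of the projection band (um), `NA` for
#'   directly rendered 2D images.
#' @return An object of class `projection2d`.
#' @export
projection2d <- function(image, source_channel, pixel_size_um,
                         origin_um = c(0, 0), band_halfwidth_um = NA_real_) {
  structure(list(image = image, source_channel = source_channel,
                 pixel_size_um = pixel_size_um, origin_um = as.numeric(origin_um),
                 band_halfwidth_um = band_halfwidth_um),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("projection2d [%s]: %d x %d px, %.2f um/px\n",
              x$source_channel, nrow(x$image), ncol(x$image), x$pixel_size_um))
  invisible(x)
}

## ---- geometry helpers -----------------------------------------------------

# Pixel-center coordinate grids (um) for an ny x nx field.
pixel_grid <- function(ny, nx, pixel_size_um, origin_um) {
  xs <- origin_um[1] + (seq_len(nx) - 0.5) * pixel_size_um
  ys <- origin_um[2] + (seq_len(ny) - 0.5) * pixel_size_um
  list(x = matrix(xs, ny, nx, byrow = TRUE), y = matrix(ys, ny, nx))
}

# Field extent covering the lattice plus a margin, origin at (-margin,-margin)
# relative to the lattice corner.
field_geometry <- function(lattice, pixel_size_um, margin_um) {
  nx <- ceiling((max(lattice$x_um) + 2 * margin_um) / pixel_size_um)
  ny <- ceiling((max(lattice$y_um) + 2 * margin_um) / pixel_size_um)
  list(ny = ny, nx = nx, origin_um = c(min(lattice$x_um) - margin_um,
                                       min(lattice$y_um) - margin_um))
}

# Distances from every pixel to the nearest and second-nearest of `pts`
# (n x 2 matrix, um). Returns list(d1, d2) matrices.
two_nearest_dist <- function(gx, gy, pts) {
  px <- as.vector(gx); py <- as.vector(gy)
  D <- sqrt(outer(px, pts[, 1], "-")^2 + outer(py, pts[, 2], "-")^2)
  if (ncol(D) == 1L) return(list(d1 = matrix(D, nrow(gx)), d2 = matrix(Inf, nrow(gx), ncol(gx))))
  i1 <- max.col(-D, ties.method = "first")
  d1 <- D[cbind(seq_along(px), i1)]
  D[cbind(seq_along(px), i1)] <- Inf
  d2 <- D[cbind(seq_along(px), max.col(-D, ties.method = "first"))]
  list(d1 = matrix(d1, nrow(gx)), d2 = matrix(d2, nrow(gx)))
}

#' Inter-column band centerlines of a lattice
#'
#' Returns the across-column coordinates (um, in the lattice's column frame)
#' of the midlines between adjacent cone columns, together with the unit
#' vectors along (`e_u`) and across (`e_v`) the columns. A point with
#' coordinates (x, y) has across-column coordinate `v = -x sin(theta) +
#' y cos(theta)` with `theta` the column direction.
#'
#' @param lattice a `mosaic_lattice`.
#' @return list with `v_mid` (numeric vector), `v_columns`, `e_u`, `e_v`.
#' @export
column_centerlines <- function(lattice) {
  theta <- attr(lattice, "column_direction_deg") * pi / 180
  e_u <- c(cos(theta), sin(theta)); e_v <- c(-sin(theta), cos(theta))
  cones <- lattice[lattice$subtype != "ROD", ]
  v <- cones$x_um * e_v[1] + cones$y_um * e_v[2]
  v_cols <- sort(vapply(split(v, cones$column_index), mean, numeric(1)))
  v_mid <- if (length(v_cols) >= 2) (v_cols[-1] + v_cols[-length(v_cols)]) / 2 else numeric(0)
  list(v_mid = unname(v_mid), v_columns = unname(v_cols), e_u = e_u, e_v = e_v)
}

# Evaluate the OLM surface depth z(x, y) (um) for a surface specification.
surface_depth <- function(gx, gy, surface_spec) {
  mode <- surface_spec$mode %||% "flat"
  z0 <- surface_spec$z0 %||% 10
  switch(mode,
    flat = matrix(z0, nrow(gx), ncol(gx)),
    tilted = {
      sl <- surface_spec$slope %||% c(0.1, 0)
      z0 + sl[1] * (gx - mean(gx[1, ])) + sl[2] * (gy - mean(gy[, 1]))
    },
    spherical_cap = {
      R <- surface_spec$radius %||% 200
      cx <- surface_spec$center[1] %||% mean(gx[1, ])
      cy <- surface_spec$center[2] %||% mean(gy[, 1])
      rho2 <- (gx - cx)^2 + (gy - cy)^2
      if (any(rho2 >= R^2)) abort("Spherical cap radius smaller than the field extent.",
                                  class = "mosaicmech_geometry_error")
      z0 + (R - sqrt(R^2 - rho2))
    },
    abort(sprintf("Unknown surface mode '%s'.", mode))
  )
}

## ---- z-stack renderer -----------------------------------------------------

default_channel_spec <- function() {
  list(zo1  = list(style = "membrane", amplitude = 1),
       red  = list(style = "soma", subtypes = "RED", amplitude = 1),
       glia = list(style = "glia", amplitude = 1))
}

#' Render a confocal-like multi-channel z-stack of a lattice
#'
#' Emulates a flat-mount confocal acquisition of the photoreceptor mosaic.
#' The apical signal is confined to a bright surface z(x, y) (flat, tilted
#' plane, or spherical cap) inside the stack. Membrane-style channels (e.g. a
#' ZO1 junction label) place intensity on the boundaries between cell
#' profiles (the ridges of the site Voronoi diagram); soma-style channels
#' place Gaussian blobs at the positions of the emitting subtypes; the glial
#' style fills thin lamellae around every profile plus thicker bright bands
#' on the inter-column midlines. Intensity falls off in z as a Gaussian of
#' width `psf_sigma_um` about the surface.
#'
#' @param lattice a `mosaic_lattice`.
#' @param surface_spec list with `mode` one of `"flat"`, `"tilted"`,
#'   `"spherical_cap"`, plus `z0` (um) and mode parameters (`slope` = c(dz/dx,
#'   dz/dy) for tilted; `radius`, optional `center` for the cap).
#' @param channel_spec named list; each element has `style`
#'   (`"membrane"|"soma"|"glia"`), optional `subtypes` (for soma) and
#'   `amplitude`. Default: `zo1` membrane, `red` soma of RED cones, `glia`.
#' @param psf_sigma_um axial Gaussian width of the rendered signal (um).
#' @param noise_sd additive Gaussian intensity noise, clipped at 0.
#' @param seed integer seed for the noise.
#' @param pixel_size_um lateral pixel size (um); default 0.2.
#' @param dz_um z-step between optical sections (um); default 1.8.
#' @param nz number of slices; chosen automatically to contain the surface
#'   when `NULL`. A surface leaving the stack is a geometry error.
#' @param margin_um lateral margin around the lattice (um); default half the
#'   lattice spacing, so border profiles match interior profile size.
#' @param wall_width_um Gaussian width of membrane walls (um).
#' @param soma_sigma_um Gaussian radius of soma blobs (um); default
#'   0.25 * spacing (half that for rods).
#' @param band_width_um full width of the inter-column glial bands (um).
#' @param lamella_amplitude relative intensity of glial lamellae vs bands.
#' @return An [image_stack].
#' @export
render_zstack <- function(lattice,
                          surface_spec = list(mode = "flat", z0 = 10),
                          channel_spec = NULL,
                          psf_sigma_um = 0.9,
                          noise_sd = 0,
                          seed = 1L,
                          pixel_size_um = 0.2,
                          dz_um = 1.8,
                          nz = NULL,
                          margin_um = NULL,
                          wall_width_um = 0.3,
                          soma_sigma_um = NULL,
                          band_width_um = 1.6,
                          lamella_amplitude = 0.6) {
  channel_spec <- channel_spec %||% default_channel_spec()
  # default margin of half a cell keeps border profiles the size of interior
  # ones, so border cells do not dilute per-profile mean intensities
  margin_um <- margin_um %||% (attr(lattice, "spacing") / 2)
  geom <- field_geometry(lattice, pixel_size_um, margin_um)
  g <- pixel_grid(geom$ny, geom$nx, pixel_size_um, geom$origin_um)
  zsurf <- surface_depth(g$x, g$y, surface_spec)

  if (is.null(nz)) nz <- ceiling((max(zsurf) + 3 * psf_sigma_um) / dz_um) + 1L
  zs <- (seq_len(nz) - 0.5) * dz_um
  if (any(zsurf <= 3 * psf_sigma_um) || any(zsurf >= nz * dz_um - 3 * psf_sigma_um)) {
    abort("OLM surface (plus 3 sigma of signal) exits the stack bounds.",
          class = "mosaicmech_geometry_error")
  }

  base <- lapply(channel_spec, function(cs) {
    render_channel_2d(lattice, g, cs,
                      wall_width_um = wall_width_um,
                      soma_sigma_um = soma_sigma_um,
                      band_width_um = band_width_um,
                      lamella_amplitude = lamella_amplitude)
  })

  ## each optical section integrates the axial Gaussian over its slab
  ## (erf difference), as a real detector does; scaled so the peak slice of a
  ## surface centered on a slice has weight ~1
  w_norm <- 2 * stats::pnorm(dz_um / 2, 0, psf_sigma_um) - 1
  channels <- with_local_seed(seed, lapply(base, function(b) {
    arr <- array(0, dim = c(nz, geom$ny, geom$nx))
    for (k in seq_len(nz)) {
      w <- (stats::pnorm(zs[k] + dz_um / 2, zsurf, psf_sigma_um) -
              stats::pnorm(zs[k] - dz_um / 2, zsurf, psf_sigma_um)) / w_norm
      sl <- b * w
      if (noise_sd > 0) sl <- pmax(sl + rnorm(length(sl), sd = noise_sd), 0)
      arr[k, , ] <- sl
    }
    arr
  }))
  image_stack(channels, voxel_size_um = c(dz_um, pixel_size_um, pixel_size_um),
              origin_um = geom$origin_um)
}

# 2D channel pattern at the surface, shared by the 3D and 2D renderers.
render_channel_2d <- function(lattice, g, cs, wall_width_um, soma_sigma_um,
                              band_width_um, lamella_amplitude) {
  amp <- cs$amplitude %||% 1
  spacing <- attr(lattice, "spacing")
  pts_all <- cbind(lattice$x_um, lattice$y_um)
  switch(cs$style,
    membrane = {
      d <- two_nearest_dist(g$x, g$y, pts_all)
      amp * exp(-0.5 * ((d$d2 - d$d1) / wall_width_um)^2)
    },
    soma = {
      subs <- cs$subtypes %||% setdiff(CONE_SUBTYPES, "ROD")
      img <- matrix(0, nrow(g$x), ncol(g$x))
      for (s in intersect(subs, unique(as.character(lattice$subtype)))) {
        pts <- pts_all[lattice$subtype == s, , drop = FALSE]
        sig <- soma_sigma_um %||% (0.25 * spacing)
        if (s == "ROD") sig <- sig / 2
        d2 <- outer(as.vector(g$x), pts[, 1], "-")^2 + outer(as.vector(g$y), pts[, 2], "-")^2
        img <- img + matrix(rowSums(exp(-d2 / (2 * sig^2))), nrow(g$x))
      }
      amp * img
    },
    glia = {
      d <- two_nearest_dist(g$x, g$y, pts_all)
      lam <- lamella_amplitude * exp(-0.5 * ((d$d2 - d$d1) / wall_width_um)^2)
      cl <- column_centerlines(lattice)
      band <- matrix(0, nrow(g$x), ncol(g$x))
      if (length(cl$v_mid)) {
        v <- g$x * cl$e_v[1] + g$y * cl$e_v[2]
        dmin <- Reduce(pmin, lapply(cl$v_mid, function(vm) abs(v - vm)))
        sigb <- band_width_um / (2 * sqrt(2 * log(2)))
        band <- exp(-0.5 * (dmin / sigb)^2)
      }
      amp * pmax(band, lam)
    },
    abort(sprintf("Unknown channel style '%s'.", cs$style))
  )
}

#' Render a 2D glial band image
#'
#' Direct 2D rendering of the Muller glial pattern at the OLM: bright straight
#' bands of width `band_width_px` on the inter-column midlines, parallel to
#' the column direction, plus thin closed lamellae of width `lamella_width_px`
#' around each profile.
#'
#' @param lattice a `mosaic_lattice`.
#' @param band_width_px full width of inter-column bands in pixels; must
#'   exceed `lamella_width_px`.
#' @param lamella_width_px width of the per-profile lamellae in pixels (>= 1).
#' @param pixel_size_um pixel size (um).
#' @param noise_sd additive Gaussian intensity noise (clipped at 0).
#' @param seed integer noise seed.
#' @param margin_um lateral margin (um).
#' @param lamella_amplitude relative lamella intensity.
#' @return A [projection2d] with `source_channel = "glia"`.
#' @export
render_glial_band_image <- function(lattice, band_width_px = 8, lamella_width_px = 2,
                                    pixel_size_um = 0.2, noise_sd = 0, seed = 1L,
                                    margin_um = 2, lamella_amplitude = 0.6) {
  if (!(band_width_px > lamella_width_px && lamella_width_px >= 1)) {
    abort("Require band_width_px > lamella_width_px >= 1.", class = "mosaicmech_sizing_error")
  }
  geom <- field_geometry(lattice, pixel_size_um, margin_um)
  g <- pixel_grid(geom$ny, geom$nx, pixel_size_um, geom$origin_um)
  img <- render_channel_2d(lattice, g,
                           list(style = "glia", amplitude = 1),
                           wall_width_um = lamella_width_px * pixel_size_um / 2,
                           soma_sigma_um = NULL,
                           band_width_um = band_width_px * pixel_size_um,
                           lamella_amplitude = lamella_amplitude)
  if (noise_sd > 0) {
    img <- with_local_seed(seed, pmax(img + rnorm(length(img), sd = noise_sd), 0))
  }
  projection2d(img, "glia", pixel_size_um, geom$origin_um)
}
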