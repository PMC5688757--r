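#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Cone subtype levels used throughout the package. The adult zebrafish retina
# carries four spectral cone classes plus rods at the outer limiting membrane.
CONE_SUBTYPES <- c("RED", "GREEN", "BLUE", "UV", "ROD")

# The 6-cone repeat motif along a column: successive Red cones are separated
# alternately by a single Blue cone and by a Green-UV-Green triplet.
COLUMN_MOTIF <- c("RED", "BLUE", "RED", "GREEN", "UV", "GREEN")

#' Generate an ideal cone lattice mosaic
#'
#' Builds the adult-type lattice mosaic of cone photoreceptors: single-cell-width
#' columns with the repeat motif Red, Blue, Red, Green, UV, Green, adjacent
#' columns phase-shifted by half a repeat unit so that UV and Blue cones
#' alternate along rows. Optionally places four rods at the corners of each UV
#' cone (at the diagonal midpoints between the UV site and its four nearest
#' Red-cone neighbors in the adjacent columns).
#'
#' Coordinates are continuous 2D positions in micrometers with the origin at
#' the lattice corner; `column_direction_deg` is the direction of the columns,
#' counterclockwise from +x. The perpendicular spacing between columns is
#' `column_gap_factor * spacing`; the default `sqrt(3)` makes the six Red
#' cones surrounding each interior UV cone equidistant (regular hexagons).
#'
#' @param n_columns number of cone columns (>= 1).
#' @param n_repeat_units number of 6-cone repeat units per column (>= 1).
#' @param spacing center-to-center distance (um) between adjacent cones along
#'   a column.
#' @param include_rods logical; add 4 rods at the corners of each UV cone.
#' @param column_direction_deg direction of the columns in degrees,
#'   counterclockwise from +x, interpreted modulo 180.
#' @param jitter_sd standard deviation (um) of isotropic Gaussian positional
#'   jitter added to every site; labels are unaffected.
#' @param seed integer seed controlling the jitter; ignored when
#'   `jitter_sd = 0`.
#' @param column_gap_factor inter-column spacing as a multiple of `spacing`.
#' @param rod_offset_factor rods sit at
#'   `uv + (+-rod_offset_factor * spacing) e_u + (+-gap/2) e_v`; the default
#'   0.5 is the diagonal midpoint toward the nearest cross-column Red cones.
#'
#' @return A tibble of class `mosaic_lattice` with columns `site_id`, `x_um`,
#'   `y_um`, `subtype`, `column_index`, `row_index`, and the generation
#'   parameters stored as attributes (`spacing`, `column_direction_deg`,
#'   `column_gap_factor`, `n_columns`, `n_repeat_units`, `include_rods`).
#' @examples
#' lat <- generate_mosaic_lattice(3, 4, spacing = 2.5, include_rods = TRUE)
#' dplyr::count(lat, subtype)
#' @export
generate_mosaic_lattice <- function(n_columns,
                                    n_repeat_units,
                                    spacing = 2.5,
                                    include_rods = FALSE,
                                    column_direction_deg = 90,
                                    jitter_sd = 0,
                                    seed = 1L,
                                    column_gap_factor = sqrt(3),
                                    rod_offset_factor = 0.5) {
  if (n_columns < 1 || n_repeat_units < 1) {
    abort("`n_columns` and `n_repeat_units` must be >= 1.", class = "mosaicmech_sizing_error")
  }
  if (spacing <= 0) {
    abort("`spacing` must be positive.", class = "mosaicmech_sizing_error")
  }
  if (jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0.", class = "mosaicmech_sizing_error")
  }
  theta <- (column_direction_deg %% 180) * pi / 180
  e_u <- c(cos(theta), sin(theta))   # along columns
  e_v <- c(-sin(theta), cos(theta))  # across columns
  gap <- column_gap_factor * spacing

  n_sites_col <- 6L * as.integer(n_repeat_units)
  cols <- seq_len(n_columns) - 1L
  rows <- seq_len(n_sites_col) - 1L

  # adjacent columns carry the motif phase-shifted by half a repeat unit
  # (3 sites), realized as a motif-index shift so all columns stay flush
  grid <- tidyr::expand_grid(column_index = cols, row_index = rows)
  grid <- grid |>
    mutate(
      u = .data$row_index * spacing,
      v = .data$column_index * gap,
      subtype = COLUMN_MOTIF[((.data$row_index + 3L * (.data$column_index %% 2L)) %% 6L) + 1L]
    )

  if (include_rods) {
    uv <- filter(grid, .data$subtype == "UV")
    offs <- tidyr::expand_grid(du = c(-1, 1) * rod_offset_factor * spacing,
                               dv = c(-1, 1) * gap / 2)
    rods <- tidyr::crossing(uv, offs) |>
      mutate(u = .data$u + .data$du, v = .data$v + .data$dv, subtype = "ROD") |>
      select(-"du", -"dv")
    grid <- bind_rows(grid, rods)
  }

  xy <- cbind(grid$u, grid$v) %*% rbind(e_u, e_v)
  grid$x_um <- xy[, 1] - min(xy[, 1])
  grid$y_um <- xy[, 2] - min(xy[, 2])

  if (jitter_sd > 0) {
    jit <- with_local_seed(seed, matrix(stats::rnorm(2L * nrow(grid), sd = jitter_sd), ncol = 2))
    grid$x_um <- grid$x_um + jit[, 1]
    grid$y_um <- grid$y_um + jit[, 2]
  }

  out <- grid |>
    arrange(.data$column_index, .data$row_index, .data$subtype) |>
    mutate(site_id = dplyr::row_number()) |>
    select("site_id", "x_um", "y_um", "subtype", "column_index", "row_index")

  structure(out,
            class = c("mosaic_lattice", class(out)),
            spacing = spacing,
            column_direction_deg = column_direction_deg %% 180,
            column_gap_factor = column_gap_factor,
            rod_offset_factor = rod_offset_factor,
            n_columns = as.integer(n_columns),
            n_repeat_units = as.integer(n_repeat_units),
            include_rods = include_rods,
            jitter_sd = jitter_sd)
}

#' Validate lattice neighbor rules
#'
#' Checks a lattice against the mosaic neighbor rules: (i) within every
#' column, successive Red cones are separated alternately by exactly one Blue
#' cone and by a Green-UV-Green triplet; (ii) when rods are present, every UV
#' cone has exactly 4 rods at its corners; (iii) each interior UV cone is
#' surrounded by 6 Red cones at equal distance (the Red-cone hexagons of the
#' adult mosaic), within `tol`.
#'
#' @param lattice a `mosaic_lattice` tibble.
#' @param tol tolerance (um) on distance equality for the hexagonality and
#'   rod-placement checks.
#' @return A list of class `lattice_validation` with elements `pass` (logical)
#'   and `violations` (tibble with columns `rule`, `site_id`, `detail`).
#' @export
validate_lattice <- function(lattice, tol = 1e-6) {
  if (!nrow(lattice)) abort("Cannot validate an empty lattice.")
  spacing <- attr(lattice, "spacing")
  gap <- attr(lattice, "column_gap_factor") * spacing
  theta <- attr(lattice, "column_direction_deg") * pi / 180
  e_u <- c(cos(theta), sin(theta))

  viol <- list()

  ## rule 1: column motif ---------------------------------------------------
  cones <- filter(lattice, .data$subtype != "ROD")
  for (ci in unique(cones$column_index)) {
    colsites <- cones |>
      filter(.data$column_index == ci) |>
      mutate(u = .data$x_um * e_u[1] + .data$y_um * e_u[2]) |>
      arrange(.data$u)
    s <- as.character(colsites$subtype)
    ok <- FALSE
    for (off in 0:5) {
      motif <- COLUMN_MOTIF[((seq_along(s) - 1L + off) %% 6L) + 1L]
      if (identical(s, motif)) { ok <- TRUE; break }
    }
    if (!ok) {
      # report first site where every rotation disagrees
      bad <- which(vapply(seq_along(s), function(i) {
        !any(vapply(0:5, function(off) s[i] == COLUMN_MOTIF[((i - 1L + off) %% 6L) + 1L], logical(1)))
      }, logical(1)))
      first_bad <- if (length(bad)) bad[1] else 1L
      viol[[length(viol) + 1L]] <- tibble(
        rule = "column_motif",
        site_id = colsites$site_id[first_bad],
        detail = sprintf("column %d does not follow the R,B,R,G,U,G motif", ci))
    }
  }

  uv <- filter(lattice, .data$subtype == "UV")
  ## rule 2: 4 rods at UV corners -------------------------------------------
  rods <- filter(lattice, .data$subtype == "ROD")
  if (nrow(rods)) {
    rod_dist <- sqrt((attr(lattice, "rod_offset_factor") * spacing)^2 + (gap / 2)^2)
    for (k in seq_len(nrow(uv))) {
      d <- sqrt((rods$x_um - uv$x_um[k])^2 + (rods$y_um - uv$y_um[k])^2)
      n_corner <- sum(d <= rod_dist + tol)
      if (n_corner != 4L) {
        viol[[length(viol) + 1L]] <- tibble(
          rule = "rod_corners", site_id = uv$site_id[k],
          detail = sprintf("UV site has %d corner rods (expected 4)", n_corner))
      }
    }
  }

  ## rule 3: hexagonality around interior UV cones --------------------------
  reds <- filter(lattice, .data$subtype == "RED")
  nc <- attr(lattice, "n_columns")
  nu <- attr(lattice, "n_repeat_units")
  # interior UV: both adjacent columns and both in-column Red neighbors exist
  interior <- uv |>
    filter(.data$column_index >= 1, .data$column_index <= nc - 2,
           .data$row_index >= 2L, .data$row_index <= 6L * nu - 3L)
  if (nrow(interior) && nrow(reds) >= 6) {
    for (k in seq_len(nrow(interior))) {
      d <- sort(sqrt((reds$x_um - interior$x_um[k])^2 + (reds$y_um - interior$y_um[k])^2))[1:6]
      if (max(d) - min(d) > tol) {
        viol[[length(viol) + 1L]] <- tibble(
          rule = "red_hexagon", site_id = interior$site_id[k],
          detail = sprintf("6 nearest Red distances span %.3g um (> tol)", max(d) - min(d)))
      }
    }
  }

  violations <- if (length(viol)) bind_rows(viol) else
    tibble(rule = character(), site_id = integer(), detail = character())
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "lattice_validation")
}

#' @export
print.lattice_validation <- function(x, ...) {
  cat(if (x$pass) "Lattice valid: all neighbor rules satisfied.\n"
      else sprintf("Lattice INVALID: %d rule violation(s).\n", nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations, ...)
  invisible(x)
}

#' Predicted ratio of Red to non-Red apical profiles
#'
#' Counts subtypes in one repeat unit of a generated ideal lattice and returns
#' the predicted ratio of Red-cone-reporter-positive to negative profiles,
#' expressed as 1:x. With cones only the repeat unit holds 2 Red and 4 other
#' cones (1:2); with four rods per UV cone it holds 2 Red and 8 other
#' profiles (1:4).
#'
#' @param include_rods logical; count the 4 rods per UV cone.
#' @return One-row tibble with `n_red`, `n_other`, `ratio_red` (always 1) and
#'   `ratio_other` (the x in 1:x).
#' @examples
#' expected_profile_ratio(include_rods = FALSE) # 1:2
#' expected_profile_ratio(include_rods = TRUE)  # 1:4
#' @export
expected_profile_ratio <- function(include_rods = FALSE) {
  unit <- generate_mosaic_lattice(1, 1, include_rods = include_rods)
  n_red <- sum(unit$subtype == "RED")
  n_other <- sum(unit$subtype != "RED")
  tibble(n_red = n_red, n_other = n_other,
         ratio_red = 1, ratio_other = n_other / n_red)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so package randomness never disturbs user code.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
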