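## ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_raster geom_line geom_path
#'   geom_hline coord_equal scale_fill_viridis_c labs facet_wrap autoplot
NULL

#' Plot a lattice mosaic
#'
#' @param object a `mosaic_lattice`.
#' @param ... unused.
#' @return A ggplot: sites colored by subtype, equal aspect.
#' @export
autoplot.mosaic_lattice <- function(object, ...) {
  sizes <- c(RED = 2.4, GREEN = 2.4, BLUE = 2.4, UV = 3, ROD = 1.2)
  ggplot(object, aes(.data$x_um, .data$y_um, colour = .data$subtype)) +
    geom_point(size = sizes[as.character(object$subtype)]) +
    ggplot2::scale_colour_manual(values = c(
      RED = "#d62728", GREEN = "#2ca02c", BLUE = "#1f77b4",
      UV = "#9467bd", ROD = "grey40")) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "subtype",
         title = "Cone lattice mosaic")
}

raster_df <- function(img, pixel_size_um, origin_um) {
  tibble(
    x_um = rep(origin_um[1] + (seq_len(ncol(img)) - 0.5) * pixel_size_um,
               each = nrow(img)),
    y_um = rep(origin_um[2] + (seq_len(nrow(img)) - 0.5) * pixel_size_um,
               times = ncol(img)),
    value = as.vector(img))
}

#' Plot a 2D projection image
#'
#' @param object a [projection2d].
#' @param ... unused.
#' @return A ggplot raster of the image in um coordinates.
#' @export
autoplot.projection2d <- function(object, ...) {
  ggplot(raster_df(object$image, object$pixel_size_um, object$origin_um),
         aes(.data$x_um, .data$y_um, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = "intensity",
         title = sprintf("Projection: %s", object$source_channel))
}

#' Plot a reconstructed OLM surface
#'
#' @param object a `surface_map`.
#' @param ... unused.
#' @return A ggplot raster of the height field (um).
#' @export
autoplot.surface_map <- function(object, ...) {
  ggplot(raster_df(object$z_um, object$pixel_size_um, object$origin_um),
         aes(.data$x_um, .data$y_um, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(option = "magma") +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = "z (µm)",
         title = "OLM surface height")
}

#' Overlay ridge lines on their score field
#'
#' @param object a `ridge_lines` tibble (from [refine_ridges()] or
#'   [filter_ridges()]).
#' @param ... unused.
#' @return A ggplot: score raster with surviving ridge lines drawn on top.
#' @export
autoplot.ridge_lines <- function(object, ...) {
  field <- attr(object, "field")
  pix <- if (nrow(object)) tidyr::unnest(select(object, "line_id", "pixels"), "pixels") else
    tibble(line_id = integer(), row = integer(), col = integer())
  p <- ggplot() + coord_equal() +
    labs(x = "x (px)", y = "y (px)", title = "Ridge lines")
  if (!is.null(field)) {
    df <- tibble(col = rep(seq_len(ncol(field$score)), each = nrow(field$score)),
                 row = rep(seq_len(nrow(field$score)), times = ncol(field$score)),
                 score = as.vector(field$score))
    p <- p + geom_raster(data = df, aes(.data$col, .data$row, fill = .data$score)) +
      scale_fill_viridis_c()
  }
  p + geom_path(data = pix, aes(.data$col, .data$row, group = .data$line_id),
                colour = "red", linewidth = 0.6)
}

#' Strain time course by axis and group
#'
#' @param ... one or more `strain_table` tibbles (rows are pooled).
#' @return A ggplot of x- and y-strain against time after ablation; the
#'   dashed line marks strain 1 (no deformation).
#' @export
plot_strain_timecourse <- function(...) {
  tbl <- bind_rows(...)
  long <- tidyr::pivot_longer(tbl, c("x_strain", "y_strain"),
                              names_to = "axis", values_to = "strain")
  ggplot(long, aes(.data$time_min, .data$strain,
                   colour = .data$group, group = interaction(.data$group, .data$axis))) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point() + geom_line() +
    facet_wrap(~axis) +
    labs(x = "time after ablation (min)", y = "stretch ratio",
         title = "Recoil strain time course")
}
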