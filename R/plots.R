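#' Map a per-cell variable with ggplot2
#'
#' Generic quick-look raster map for any per-cell table produced by the
#' package (climatologies, index tables, classified maps, change maps).
#'
#' @param data Tibble with `x`, `y` and the variable.
#' @param var Column to map (tidy-eval).
#' @param discrete Draw as discrete classes (factor fill)?
#' @return A ggplot object.
#' @examples
#' tr <- make_terrain(grid_geometry(20, 20, 1000), 800, seed = 1)
#' plot_grid_map(tr, elevation)
#' @export
plot_grid_map <- function(data, var, discrete = FALSE) {
  v <- rlang::enquo(var)
  fill <- if (discrete) rlang::quo(factor(!!v)) else v
  ggplot2::ggplot(data, ggplot2::aes(.data$x, .data$y, fill = !!fill)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = rlang::as_label(v), x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Map total bioclimatic class change
#'
#' @param change Output of [index_change()].
#' @return A ggplot object: cells coloured by the summed number of category
#'   changes across the three indices.
#' @export
plot_change_map <- function(change) {
  plot_grid_map(change, .data$total_change, discrete = TRUE) +
    ggplot2::scale_fill_viridis_d(option = "inferno", direction = -1) +
    ggplot2::labs(fill = "classes of change")
}

#' Climate-cube scatter of isobioclimates
#'
#' Projects the 3-D climate cube onto the ombrotype-continentality plane,
#' faceting by thermotype, with point size on a log-area scale and colour by
#' period - the tabular equivalent of a 3-D climate-space cube figure.
#'
#' @param space Output of [climate_space()].
#' @return A ggplot object.
#' @export
plot_climate_space <- function(space) {
  ggplot2::ggplot(space, ggplot2::aes(.data$io_cat, .data$ic_cat,
                                      size = .data$area_km2,
                                      colour = .data$period)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_continuous(trans = "log10") +
    ggplot2::facet_wrap(~tmo_cat, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "ombrotype category", y = "continentality category",
                  size = expression(area ~ (km^2))) +
    ggplot2::theme_minimal()
}

#' CCA biplot
#'
#' Species scores (weighted-average form) with the canonical-coefficient
#' arrows of the environmental variables superimposed.
#'
#' @param object A fitted [cca_bioclim()] object.
#' @param axes Length-2 integer vector of axes to draw.
#' @param arrow_scale Multiplier applied to the variable arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bioclim_cca <- function(object, axes = c(1, 2), arrow_scale = 1, ...) {
  stopifnot(length(axes) == 2, max(axes) <= length(object$eigenvalues))
  sp <- tibble::as_tibble(object$species_scores[, axes, drop = FALSE],
                          rownames = "species")
  names(sp)[2:3] <- c("a1", "a2")
  ev <- tibble::as_tibble(object$coefficients[, axes, drop = FALSE],
                          rownames = "variable")
  names(ev)[2:3] <- c("a1", "a2")
  ev[2:3] <- ev[2:3] * arrow_scale
  labs <- sprintf("CCA%d (%.3f)", axes, object$eigenvalues[axes])
  ggplot2::ggplot(sp, ggplot2::aes(.data$a1, .data$a2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$species), size = 3) +
    ggplot2::geom_segment(
      data = ev, ggplot2::aes(x = 0, y = 0, xend = .data$a1, yend = .data$a2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "red3"
    ) +
    ggplot2::geom_text(data = ev,
                       ggplot2::aes(label = .data$variable),
                       colour = "red3", vjust = -0.6, size = 3.2) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}
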