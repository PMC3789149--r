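#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-species density trajectories
#'
#' @param object A `lattice_sim` or `mf_trajectory`.
#' @param ... Unused.
#' @return A ggplot: density of each species (empty sites dashed) over time.
#' @export
autoplot.lattice_sim <- function(object, ...) {
  plot_series(tidy(object), "step")
}

#' @export
autoplot.mf_trajectory <- function(object, ...) {
  plot_series(tidy(object), "t")
}

plot_series <- function(long, time_col) {
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data[[time_col]], y = .data$density,
                               colour = .data$species,
                               linetype = .data$species == "e")) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = if (time_col == "t") "time (MC steps)" else "MC step",
                  y = "density", colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot richness versus nutrient level
#'
#' The paradox-of-enrichment profile: richness peaks at low nutrient levels
#' and collapses as nutrients rise.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- tibble::tibble(P = object$P, richness = object$richness)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$P, y = .data$richness)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nutrient level P", y = "species richness") +
    ggplot2::theme_minimal()
}

#' Plot a lattice snapshot
#'
#' @param state A `lattice_state` or integer matrix.
#' @return A ggplot raster of the grid (empty sites white).
#' @export
plot_snapshot <- function(state) {
  grid <- if (inherits(state, "lattice_state")) state$grid else state
  L <- nrow(grid)
  df <- tibble::tibble(
    row = rep(seq_len(L), times = ncol(grid)),
    col = rep(seq_len(ncol(grid)), each = L),
    species = factor(as.vector(grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$species)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c("0" = "white",
                 stats::setNames(grDevices::hcl.colors(
                   max(1L, max(grid)), "Dark 3"),
                   as.character(seq_len(max(1L, max(grid))))))) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
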