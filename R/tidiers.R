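#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lattice simulation into long densities
#'
#' @param x A `lattice_sim`.
#' @param ... Unused.
#' @return A tibble `step, species, density` with `species = "e"` for empty
#'   sites.
#' @export
tidy.lattice_sim <- function(x, ...) {
  series_long(x$series, "step")
}

#' @export
tidy.mf_trajectory <- function(x, ...) {
  series_long(x, "t")
}

series_long <- function(df, time_col) {
  cols <- setdiff(names(df), time_col)
  purrr::map_dfr(cols, function(cn) {
    tibble::tibble(!!time_col := df[[time_col]],
                   species = sub("^x_", "", cn),
                   density = df[[cn]])
  })
}

#' One-row summary of a lattice simulation
#'
#' @param x A `lattice_sim`.
#' @param ... Unused.
#' @return A tibble with `mode`, `L`, `P`, `steps`, final `richness`,
#'   `total_density` and `empty_density`.
#' @export
glance.lattice_sim <- function(x, ...) {
  final <- x$series[nrow(x$series), ]
  xs <- as.numeric(final[grep("^x_", names(final))])
  tibble::tibble(mode = x$config$mode, L = x$config$L, P = x$config$P,
                 steps = x$config$steps, richness = sum(xs > 0),
                 total_density = sum(xs), empty_density = final$e)
}

#' Survival table of a threshold scan
#'
#' @param x A `threshold_estimate`.
#' @param ... Unused.
#' @return The per-grid-value survival tibble (`b`, `n_survived`,
#'   `replicates`, `frac`).
#' @export
tidy.threshold_estimate <- function(x, ...) x$survival

#' @export
glance.threshold_estimate <- function(x, ...) {
  tibble::tibble(mode = x$mode, mortality = x$mortality,
                 estimate = x$estimate, L = x$L, steps = x$steps,
                 replicates = x$replicates)
}
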