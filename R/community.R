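#' Nutrient-dependent logistic birth rate
#'
#' Birth probability per trial as a function of the nutrient level `P`,
#' following a three-parameter logistic curve anchored at `(0, b0)` and
#' saturating at `b_max`:
#' \deqn{b(P) = \frac{b_{max}}{1 + C e^{-s P}}, \qquad C = b_{max}/b_0 - 1,}
#' so that `b(0) = b0` exactly and `b(P) -> b_max` as `P -> Inf`.  For the
#' nutrient ranges of interest (`P >= 14`) the curve behaves like a Monod
#' saturation curve.  The curve is strictly increasing in `P`.
#'
#' @param P Nutrient level(s), non-negative.
#' @param b_max Maximum birth probability in `(0, 1]`.
#' @param steepness Positive logistic rate constant (per nutrient unit).
#' @param b0 Birth probability at `P = 0`; default `1e-6`.
#' @return Birth probabilities, same length as `P` (vectorised over `P` and
#'   the parameters under the usual recycling rules).
#' @examples
#' logistic_birth(0, b_max = 0.9, steepness = 1)      # = 1e-6
#' logistic_birth(14:16, b_max = 0.9, steepness = 1)
#' @export
logistic_birth <- function(P, b_max, steepness, b0 = 1e-6) {
  if (any(P < 0)) stop("nutrient level P must be non-negative", call. = FALSE)
  if (any(b0 <= 0) || any(b_max <= b0) || any(b_max > 1))
    stop("parameters must satisfy 0 < b0 < b_max <= 1", call. = FALSE)
  if (any(steepness <= 0)) stop("steepness must be positive", call. = FALSE)
  C <- b_max / b0 - 1
  b_max / (1 + C * exp(-steepness * P))
}

#' Birth rates of a whole community at given nutrient levels
#'
#' Tidy evaluation of every species' birth curve at each requested nutrient
#' level.
#'
#' @param community A community tibble from [default_community()] or
#'   [read_community()].
#' @param P Vector of nutrient levels.
#' @return A tibble with columns `species_id`, `P`, `birth`.
#' @export
birth_rates <- function(community, P) {
  stopifnot(is.data.frame(community))
  purrr::map_dfr(P, function(p) {
    tibble::tibble(
      species_id = community$species_id,
      P = p,
      birth = logistic_birth(p, community$b_max, community$steepness,
                             community$b0)
    )
  })
}

#' Generate a community of competing species with a birth-rate tradeoff
#'
#' Builds `N` logistic birth curves that all pass through one common pivot
#' point `(pivot_P, pivot_b)` but saturate at pairwise distinct `b_max`
#' values.  Because the curves share a pivot, the ranking of birth rates below
#' the pivot is the exact reverse of the ranking above it (the tradeoff: the
#' best competitor under eutrophic conditions is the worst under oligotrophic
#' conditions), curves are nearly equal just below the pivot, and they diverge
#' increasingly above it.
#'
#' For each species the steepness is solved in closed form from
#' `logistic_birth(pivot_P) = pivot_b`:
#' \deqn{s_i = \left[\log(b_{max,i}/b_0 - 1) -
#'   \log(b_{max,i}/b_{pivot} - 1)\right] / P_{pivot}.}
#'
#' Defaults place the pivot at `P = 14.2` with common birth rate `0.545`, just
#' above the local-interaction extinction threshold (about 0.53 at mortality
#' 0.3), and spread `b_max` evenly over `[0.60, 0.90]` (descending, so species
#' 1 has the largest `b_max`).
#'
#' @param N Number of species.
#' @param pivot_P Nutrient level of the common crossing point.
#' @param pivot_b Common birth probability at the pivot; must exceed `b0` and
#'   be below every `b_max`.
#' @param b_max_values Descending vector of distinct saturation birth
#'   probabilities, length `N`.
#' @param b0 Shared birth probability at `P = 0`.
#' @param mortality Shared per-trial death probability (0.3 for local
#'   interaction, 0.5 for global, following the convention that the two modes'
#'   extinction thresholds then nearly coincide).
#' @return A tibble of class `community` with columns `species_id`, `b_max`,
#'   `steepness`, `b0`, `mortality` and attributes `pivot_P`, `pivot_b`.
#' @examples
#' comm <- default_community(10)
#' birth_rates(comm, c(14, 14.2, 16))
#' @export
default_community <- function(N = 10, pivot_P = 14.2, pivot_b = 0.545,
                              b_max_values = seq(0.90, 0.60,
                                                 length.out = N),
                              b0 = 1e-6, mortality = 0.3) {
  stopifnot(N >= 1, length(b_max_values) == N)
  if (anyDuplicated(b_max_values) && N > 1)
    stop("b_max values must be pairwise distinct", call. = FALSE)
  if (pivot_b <= b0 || pivot_b >= min(b_max_values))
    stop("infeasible parameters: need b0 < pivot_b < min(b_max)",
         call. = FALSE)
  if (mortality < 0 || mortality > 1)
    stop("mortality must lie in [0, 1]", call. = FALSE)
  steepness <- (log(b_max_values / b0 - 1) -
                  log(b_max_values / pivot_b - 1)) / pivot_P
  out <- tibble::tibble(
    species_id = seq_len(N),
    b_max = b_max_values,
    steepness = steepness,
    b0 = b0,
    mortality = mortality
  )
  new_community(out, pivot_P = pivot_P, pivot_b = pivot_b)
}

new_community <- function(df, pivot_P = NA_real_, pivot_b = NA_real_) {
  structure(df,
            pivot_P = pivot_P, pivot_b = pivot_b,
            class = c("community", class(tibble::tibble())))
}

#' Check the birth-rate tradeoff of a community
#'
#' `TRUE` iff the ranking of species by birth rate at `P_low` is the exact
#' reverse of the (strict) ranking at `P_high`, and the spread (max - min) of
#' birth rates at `P_high` exceeds the spread at `P_low` — i.e. rates are
#' close together under low nutrients and widely different under high
#' nutrients, with the ordering flipped.
#'
#' @param community A community tibble.
#' @param P_low,P_high Nutrient levels bracketing the crossing region.
#' @return Logical scalar.
#' @export
tradeoff_check <- function(community, P_low, P_high) {
  stopifnot(P_low < P_high)
  bl <- logistic_birth(P_low, community$b_max, community$steepness,
                       community$b0)
  bh <- logistic_birth(P_high, community$b_max, community$steepness,
                       community$b0)
  if (anyDuplicated(bl) || anyDuplicated(bh)) return(FALSE)
  ordering_reversed <- identical(order(bl), rev(order(bh)))
  ordering_reversed && (max(bh) - min(bh)) > (max(bl) - min(bl))
}

#' Write / read a community as CSV
#'
#' Plain CSV with header `species_id,b_max,steepness,b0,mortality`, one row
#' per species.  The pivot attributes are not serialised (they are derivable
#' from any two curves and only used at construction time).
#'
#' @param community A community tibble.
#' @param path File path.
#' @return `write_community()` returns `path` invisibly; `read_community()`
#'   returns a community tibble.
#' @export
write_community <- function(community, path) {
  readr::write_csv(
    community[, c("species_id", "b_max", "steepness", "b0", "mortality")],
    path)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = "idddd")
  need <- c("species_id", "b_max", "steepness", "b0", "mortality")
  if (!identical(names(df), need))
    stop("community CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  new_community(df)
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community of %d species>", nrow(x)))
  if (is.finite(attr(x, "pivot_P")))
    cat(sprintf("  pivot: b = %.4g at P = %.4g",
                attr(x, "pivot_b"), attr(x, "pivot_P")))
  cat("\n")
  NextMethod()
}
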