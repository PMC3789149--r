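#' Mean-field dynamics of the multi-species contact process
#'
#' Under global interaction the lattice dynamics lose spatial correlation and
#' the per-species densities `x_i` follow
#' \deqn{\dot x_i = -m_i x_i + b_i x_i e, \qquad e = 1 - \sum_j x_j,}
#' the competition-for-space Lotka–Volterra system.  `mf_rhs()` evaluates the
#' right-hand side; time is measured in Monte Carlo steps.
#'
#' @param x Density vector, `x >= 0`, `sum(x) <= 1`.
#' @param birth,mortality Per-species rate vectors (probabilities per step).
#' @return Derivative vector `dx/dt`.
#' @examples
#' mf_rhs(0.25, birth = 0.6, mortality = 0.3)  # 0.0375
#' @export
mf_rhs <- function(x, birth, mortality) {
  if (any(x < 0) || sum(x) > 1 + 1e-12)
    stop("x must be a point on the density simplex", call. = FALSE)
  e <- 1 - sum(x)
  x * (birth * e - mortality)
}

#' Integrate the mean-field system
#'
#' Fixed-step classical Runge–Kutta (RK4) integration of [mf_rhs()],
#' clipping densities at 0 after each step (extinction is absorbing and
#' round-off must not resurrect a species).  A fixed step keeps trajectories
#' bit-reproducible; the dynamics are non-stiff with rates at most 1, so
#' `dt = 0.01` gives errors far below the lattice sampling noise.
#'
#' @param x0 Initial densities on the simplex.
#' @param birth,mortality Per-species rate vectors.
#' @param T Integration horizon (Monte Carlo steps).
#' @param dt Step size.
#' @param record_every Record interval in units of `dt` steps.
#' @return A tibble of class `mf_trajectory`: columns `t`, `x_1..x_N`, `e`.
#' @examples
#' tr <- integrate_mf(0.01, birth = 0.6, mortality = 0.3, T = 100)
#' utils::tail(tr, 1)  # approaches 1 - m/b = 0.5
#' @export
integrate_mf <- function(x0, birth, mortality, T, dt = 0.01,
                         record_every = max(1L, floor(1 / dt))) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(x0 < 0) || sum(x0) > 1 + 1e-12)
    stop("x0 must lie on the density simplex", call. = FALSE)
  n_steps <- ceiling(T / dt)
  N <- length(x0)
  rhs <- function(x) x * (birth * (1 - sum(x)) - mortality)
  n_rec <- n_steps %/% record_every + 2L
  out <- matrix(NA_real_, n_rec, N + 1)
  x <- as.numeric(x0)
  out[1, ] <- c(0, x)
  r <- 1L
  for (k in seq_len(n_steps)) {
    k1 <- rhs(x)
    k2 <- rhs(pmax(x + dt / 2 * k1, 0))
    k3 <- rhs(pmax(x + dt / 2 * k2, 0))
    k4 <- rhs(pmax(x + dt * k3, 0))
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (k %% record_every == 0 || k == n_steps) {
      r <- r + 1L
      out[r, ] <- c(k * dt, x)
    }
  }
  out <- out[seq_len(r), , drop = FALSE]
  tr <- tibble::as_tibble(stats::setNames(
    as.data.frame(cbind(out, 1 - rowSums(out[, -1, drop = FALSE]))),
    c("t", paste0("x_", seq_len(N)), "e")))
  class(tr) <- c("mf_trajectory", class(tr))
  tr
}

#' Single-species mean-field equilibrium
#'
#' For one species the mean-field system reduces to logistic growth with
#' carrying density `1 - m/b`; below the mean-field persistence threshold
#' `b = m` the only equilibrium is extinction.
#'
#' @param b,m Birth and death probabilities per step (`b > 0`).
#' @return `max(0, 1 - m/b)`.
#' @export
single_species_equilibrium <- function(b, m) {
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  pmax(0, 1 - m / b)
}

#' Map two competing species to Lotka–Volterra form
#'
#' Rewriting \eqn{\dot x_i = x_i(b_i(1 - x_1 - x_2) - m_i)} as
#' \eqn{\dot x_i = R_i x_i (1 - (x_1 + x_2)/K_i)} gives the intrinsic growth
#' rate \eqn{R_i = b_i - m_i} and carrying density
#' \eqn{K_i = (b_i - m_i)/b_i}: factor out \eqn{x_i} and \eqn{R_i}, leaving
#' \eqn{1 - (x_1+x_2)\, b_i/(b_i - m_i)}.  `K_i` coincides with
#' [single_species_equilibrium()], so the species with the larger
#' single-species equilibrium excludes the other.
#'
#' @param b1,m1,b2,m2 Birth and death rates of the two species.
#' @return A two-row tibble `species, b, m, R, K`.
#' @export
lv_mapping <- function(b1, m1, b2, m2) {
  if (b1 <= 0 || b2 <= 0) stop("birth rates must be positive", call. = FALSE)
  b <- c(b1, b2); m <- c(m1, m2)
  R <- b - m
  tibble::tibble(species = 1:2, b = b, m = m, R = R, K = R / b)
}

#' Classify the two-species mean-field equilibrium
#'
#' The four stationary classes of two-species competition for space:
#' \describe{
#'   \item{both_extinct}{both intrinsic growth rates `R_i = b_i - m_i <= 0`.}
#'   \item{species1_only / species2_only}{only one `R_i > 0`, or both positive
#'     with that species holding the strictly larger carrying density `K_i`.
#'     With both `R_i > 0` the coexistence conditions (each species able to
#'     invade the other's equilibrium) cannot hold simultaneously for this
#'     competition structure, so the larger-`K` species always excludes the
#'     other.}
#'   \item{degenerate}{`K_1 = K_2 > 0`: a structurally unstable tie along a
#'     line of neutral equilibria; reported rather than resolved.}
#' }
#'
#' Species can be given either as rate pairs or as community rows plus a
#' nutrient level via [classify_community_pair()].
#'
#' @inheritParams lv_mapping
#' @return One of `"coexist"`, `"species1_only"`, `"species2_only"`,
#'   `"both_extinct"`, `"degenerate"` (`"coexist"` is never produced for
#'   distinct positive `K`; it is kept in the vocabulary for completeness).
#' @export
classify_equilibrium <- function(b1, m1, b2, m2) {
  lv <- lv_mapping(b1, m1, b2, m2)
  pos <- lv$R > 0
  if (!any(pos)) return("both_extinct")
  if (pos[1] && !pos[2]) return("species1_only")
  if (pos[2] && !pos[1]) return("species2_only")
  if (lv$K[1] == lv$K[2]) return("degenerate")
  if (lv$K[1] > lv$K[2]) "species1_only" else "species2_only"
}

#' @rdname classify_equilibrium
#' @param community A community tibble.
#' @param i,j Row indices of the two species.
#' @param P Nutrient level fixing the birth rates.
#' @export
classify_community_pair <- function(community, i, j, P) {
  bi <- logistic_birth(P, community$b_max[i], community$steepness[i],
                       community$b0[i])
  bj <- logistic_birth(P, community$b_max[j], community$steepness[j],
                       community$b0[j])
  classify_equilibrium(bi, community$mortality[i], bj, community$mortality[j])
}
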