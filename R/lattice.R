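#' Simulation configuration
#'
#' Bundles the knobs of one lattice run.  Defaults follow the standard
#' full-size setup (`L = 1000`, 20000 Monte Carlo steps); experiments in this
#' package usually run a scaled-down `L = 200`, 5000-step configuration that
#' preserves the qualitative phase structure at desk-scale runtimes.
#'
#' @param L Lattice side length (the lattice has `L^2` sites, periodic
#'   boundaries).
#' @param steps Number of Monte Carlo steps; one step is `L^2` paired
#'   death/birth trials.
#' @param mode `"local"` (birth target is a von Neumann neighbour of the
#'   parent) or `"global"` (birth target is a second uniformly drawn cell).
#' @param P Nutrient level, mapped to per-species birth probabilities through
#'   [logistic_birth()].
#' @param seed Integer RNG seed; every random draw in the run derives from it.
#' @param initial_occupancy Fraction of sites occupied at step 0, in `(0, 1]`.
#' @param record_every Interval (in steps) between density records; step 0 and
#'   the final step are always recorded.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 1000, steps = 20000, mode = c("local", "global"),
                       P = 14.2, seed = 1, initial_occupancy = 0.3,
                       record_every = 10) {
  mode <- match.arg(mode)
  if (L < 2) stop("L must be at least 2", call. = FALSE)
  if (steps < 0) stop("steps must be non-negative", call. = FALSE)
  if (initial_occupancy <= 0 || initial_occupancy > 1)
    stop("initial_occupancy must lie in (0, 1]", call. = FALSE)
  if (P < 0) stop("P must be non-negative", call. = FALSE)
  if (record_every < 1) stop("record_every must be >= 1", call. = FALSE)
  structure(list(L = as.integer(L), steps = as.integer(steps), mode = mode,
                 P = P, seed = as.integer(seed),
                 initial_occupancy = initial_occupancy,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Initialise a lattice
#'
#' Occupies `floor(initial_occupancy * L^2)` uniformly random sites, split as
#' evenly as possible among the `N` species (any remainder goes to the
#' lowest-numbered species).  Deterministic given `cfg$seed`; the global RNG
#' state is left untouched.
#'
#' @param cfg A [sim_config()].
#' @param community A community tibble; `nrow(community)` species.
#' @return A `lattice_state`: list with `grid` (`L x L` integer matrix, 0 =
#'   empty) and `step_count = 0`.
#' @export
init_lattice <- function(cfg, community) {
  L <- cfg$L
  N <- nrow(community)
  n_occ <- floor(cfg$initial_occupancy * L^2)
  per <- rep(n_occ %/% N, N)
  extra <- n_occ %% N
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  grid <- withr::with_seed(cfg$seed, {
    cells <- sample.int(L^2, n_occ)
    g <- integer(L^2)
    g[cells] <- rep(community$species_id, times = per)
    g
  })
  new_lattice_state(matrix(grid, L, L), 0L)
}

new_lattice_state <- function(grid, step_count = 0L) {
  structure(list(grid = grid, step_count = as.integer(step_count)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  L <- nrow(x$grid)
  occ <- sum(x$grid > 0)
  cat(sprintf("<lattice_state %dx%d, step %d, density %.4f, richness %d>\n",
              L, L, x$step_count, occ / L^2, richness(x)))
  invisible(x)
}

#' Single death / birth trials (reference semantics)
#'
#' One trial of each elementary reaction, written in plain R against R's own
#' RNG.  These define the per-trial semantics that the compiled Monte Carlo
#' kernel repeats `L^2` times per step; they are exposed for inspection and
#' unit testing, not for production runs.
#'
#' `death_trial()` picks one uniform cell; if occupied by species `i` it is
#' emptied with probability `mortality[i]`.  `birth_trial()` picks an ordered
#' (parent, target) pair — a uniform cell plus one of its four von Neumann
#' neighbours in local mode, or two distinct uniform cells in global mode —
#' and, iff the pair reads (occupied by `i`, empty), fills the target with
#' species `i` with probability `birth[i]`.
#'
#' @param state A `lattice_state`.
#' @param mortality,birth Per-species probability vectors.
#' @param mode `"local"` or `"global"`.
#' @return The updated `lattice_state`.
#' @export
death_trial <- function(state, mortality) {
  g <- state$grid
  idx <- sample.int(length(g), 1)
  sp <- g[idx]
  if (sp > 0 && stats::runif(1) < mortality[sp]) {
    g[idx] <- 0L
    state$grid <- g
  }
  state
}

#' @rdname death_trial
#' @export
birth_trial <- function(state, birth, mode = c("local", "global")) {
  mode <- match.arg(mode)
  g <- state$grid
  L <- nrow(g)
  p <- sample.int(L^2, 1)
  if (mode == "local") {
    r <- (p - 1) %% L
    c <- (p - 1) %/% L
    dir <- sample.int(4, 1)
    if (dir == 1) r <- (r - 1) %% L
    else if (dir == 2) r <- (r + 1) %% L
    else if (dir == 3) c <- (c - 1) %% L
    else c <- (c + 1) %% L
    t <- r + c * L + 1
  } else {
    repeat {
      t <- sample.int(L^2, 1)
      if (t != p) break
    }
  }
  sp <- g[p]
  if (sp > 0 && g[t] == 0 && stats::runif(1) < birth[sp]) {
    g[t] <- sp
    state$grid <- g
  }
  state
}

# Internal: run the compiled kernel on a grid with explicit rate vectors.
run_lattice <- function(grid, birth, death, mode, steps, record_every, seed) {
  .run_lattice_cpp(grid, as.numeric(birth), as.numeric(death),
                   identical(mode, "local"), as.integer(steps),
                   as.integer(record_every), as.numeric(seed))
}

#' Advance a lattice by Monte Carlo steps
#'
#' Runs `n_steps` Monte Carlo steps (each `L^2` death-then-birth trial pairs)
#' with the compiled kernel.  Randomness comes from a dedicated stream seeded
#' by `seed`, so successive calls need distinct seeds to be independent.
#'
#' @inheritParams death_trial
#' @param birth,mortality Per-species probability vectors.
#' @param n_steps Number of Monte Carlo steps.
#' @param seed Seed for the kernel's RNG stream.
#' @return The updated `lattice_state` with `step_count` advanced.
#' @export
mc_step <- function(state, birth, mortality, mode = c("local", "global"),
                    n_steps = 1, seed = 1) {
  mode <- match.arg(mode)
  res <- run_lattice(state$grid, birth, mortality, mode, n_steps,
                     record_every = max(n_steps, 1), seed = seed)
  new_lattice_state(res$grid, state$step_count + n_steps)
}

#' Run a full lattice simulation
#'
#' Initialises the lattice from `cfg`, maps the nutrient level `cfg$P` to
#' per-species birth probabilities through [logistic_birth()], and runs
#' `cfg$steps` Monte Carlo steps, recording densities every
#' `cfg$record_every` steps.  Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param community A community tibble.
#' @param birth Optional constant per-species birth probabilities overriding
#'   the nutrient mapping (used e.g. by [estimate_threshold()]).
#' @return A list of class `lattice_sim` with elements
#'   \describe{
#'     \item{series}{tibble `step, x_1..x_N, e` of densities (fractions of
#'       `L^2`); at every record `e + sum(x_i) = 1` exactly.}
#'     \item{state}{final `lattice_state`.}
#'     \item{config, community}{the inputs.}
#'   }
#' @examples
#' comm <- default_community(3)
#' sim <- run_simulation(sim_config(L = 50, steps = 100, P = 15,
#'                                  seed = 42, record_every = 20), comm)
#' glance(sim)
#' @export
run_simulation <- function(cfg, community, birth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- nrow(community)
  if (is.null(birth))
    birth <- logistic_birth(cfg$P, community$b_max, community$steepness,
                            community$b0)
  state <- init_lattice(cfg, community)
  res <- run_lattice(state$grid, birth, community$mortality, cfg$mode,
                     cfg$steps, cfg$record_every, cfg$seed)
  rec <- res$records
  L2 <- cfg$L^2
  series <- tibble::as_tibble(
    stats::setNames(as.data.frame(cbind(rec[, 1, drop = FALSE],
                                        rec[, -1, drop = FALSE] / L2)),
                    c("step", paste0("x_", seq_len(N)), "e")))
  structure(list(series = series,
                 state = new_lattice_state(res$grid, cfg$steps),
                 config = cfg, community = community, birth = birth),
            class = "lattice_sim")
}

#' @export
print.lattice_sim <- function(x, ...) {
  cat(sprintf("<lattice_sim %s, L = %d, P = %.3g, %d steps, final richness %d>\n",
              x$config$mode, x$config$L, x$config$P, x$config$steps,
              richness(x$state)))
  invisible(x)
}

#' Species richness
#'
#' Number of species with at least one individual.  For a simulation or a
#' density series, richness is evaluated per record.
#'
#' @param x A `lattice_state`, integer matrix, `lattice_sim`, or a density
#'   series tibble with `x_*` columns.
#' @return Integer (state/matrix) or integer vector (series, one per record).
#' @export
richness <- function(x) UseMethod("richness")

#' @export
richness.lattice_state <- function(x) richness(x$grid)

#' @export
richness.matrix <- function(x) length(setdiff(unique(as.vector(x)), 0L))

#' @export
richness.lattice_sim <- function(x) richness(x$state)

#' @export
richness.data.frame <- function(x) {
  xs <- as.matrix(x[, grep("^x_", names(x)), drop = FALSE])
  as.integer(rowSums(xs > 0))
}

#' Adjacency statistics of a lattice snapshot
#'
#' Classifies all `2 L^2` von-Neumann-adjacent cell pairs (each cell paired
#' with its right and down neighbour, periodic boundaries) into same-species,
#' cross-species, species–empty and empty–empty pairs.  Clumped spatial
#' patterns show up as an excess of same-species pairs over the random
#' expectation; the cross-species count measures how often competitors
#' actually touch.
#'
#' @param x A `lattice_state` or integer matrix.
#' @return A one-row tibble with the four pair counts; they sum to `2 L^2`.
#' @export
adjacency_stats <- function(x) {
  grid <- if (inherits(x, "lattice_state")) x$grid else x
  counts <- .adjacency_cpp(grid)
  tibble::as_tibble(as.list(counts))
}

#' Estimate the extinction threshold of the single-species contact process
#'
#' Scans a grid of constant birth probabilities (bypassing the nutrient
#' mapping): for each `b`, runs `replicates` seeded single-species
#' simulations and marks the level as persistent when the final density is
#' positive in a strict majority of replicates.  The estimate is the smallest
#' grid value with majority persistence.  Survival probability is
#' non-decreasing in `b`, so the scan brackets a unique transition.
#'
#' @param mode `"local"` or `"global"`.
#' @param mortality Per-trial death probability.
#' @param L Lattice side length.
#' @param steps Monte Carlo steps per run.
#' @param b_grid Ascending vector of birth probabilities in `(0, 1)`.
#' @param replicates Runs per grid value.
#' @param seed Base seed; replicate `j` at grid index `i` uses
#'   `seed + 1000 * i + j`.
#' @param initial_occupancy Starting density.
#' @return A list of class `threshold_estimate` with `estimate` (the critical
#'   birth probability) and a `survival` tibble (`b`, `n_survived`,
#'   `replicates`, `frac`).  [tidy()] returns the survival table, [glance()]
#'   a one-row summary.
#' @export
estimate_threshold <- function(mode = c("local", "global"), mortality,
                               L = 200, steps = 5000,
                               b_grid = seq(0.45, 0.65, by = 0.01),
                               replicates = 5, seed = 1,
                               initial_occupancy = 0.3) {
  mode <- match.arg(mode)
  if (is.unsorted(b_grid, strictly = TRUE) ||
      any(b_grid <= 0) || any(b_grid >= 1))
    stop("b_grid must be strictly ascending within (0, 1)", call. = FALSE)
  comm <- single_species_community(mortality)
  survived <- vapply(seq_along(b_grid), function(i) {
    sum(vapply(seq_len(replicates), function(j) {
      cfg <- sim_config(L = L, steps = steps, mode = mode, P = 0,
                        seed = seed + 1000L * i + j,
                        initial_occupancy = initial_occupancy,
                        record_every = steps)
      sim <- run_simulation(cfg, comm, birth = b_grid[i])
      sum(sim$state$grid > 0) > 0
    }, logical(1)))
  }, integer(1))
  surv <- tibble::tibble(b = b_grid, n_survived = survived,
                         replicates = replicates,
                         frac = survived / replicates)
  persistent <- surv$frac > 0.5
  if (!any(persistent))
    stop("bracket failure: no grid value shows majority persistence",
         call. = FALSE)
  if (all(persistent))
    stop("bracket failure: every grid value shows majority persistence",
         call. = FALSE)
  structure(list(estimate = b_grid[which(persistent)[1]], survival = surv,
                 mode = mode, mortality = mortality, L = L, steps = steps,
                 replicates = replicates, seed = seed),
            class = "threshold_estimate")
}

# Degenerate one-species community with a fixed mortality; birth comes from
# the constant-b override, so the curve parameters are placeholders.
single_species_community <- function(mortality) {
  new_community(tibble::tibble(species_id = 1L, b_max = 0.99,
                               steepness = 1, b0 = 1e-6,
                               mortality = mortality))
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate %s: b_c = %.3f (m = %.2f, L = %d, %d steps, %d reps)>\n",
    x$mode, x$estimate, x$mortality, x$L, x$steps, x$replicates))
  invisible(x)
}
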