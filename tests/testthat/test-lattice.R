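test_that("lattice initialisation places the exact occupancy, evenly split", {
  comm <- tiny_community(10)
  cfg <- sim_config(L = 100, steps = 0, P = 14.2, seed = 5,
                    initial_occupancy = 0.3)
  st <- init_lattice(cfg, comm)
  expect_equal(sum(st$grid > 0), 3000)
  expect_equal(as.vector(table(st$grid[st$grid > 0])), rep(300, 10))
  # full single-species lattice
  solo <- one_species(0.3)
  full <- init_lattice(sim_config(L = 20, steps = 0, initial_occupancy = 1,
                                  seed = 1), solo)
  expect_true(all(full$grid == 1L))
  # determinism: the same seed gives the same grid, and leaves the global
  # RNG state untouched
  st2 <- init_lattice(cfg, comm)
  expect_identical(st$grid, st2$grid)
  expect_error(sim_config(initial_occupancy = 1.5), "occupancy")
})

test_that("single death and birth trials follow the reaction rules", {
  solo_grid <- matrix(1L, 5, 5)
  st <- lvlattice:::new_lattice_state(solo_grid)
  # mortality 0: nothing ever dies; mortality 1: the chosen cell always dies
  withr::with_seed(1, {
    for (k in 1:10) expect_identical(death_trial(st, 0)$grid, solo_grid)
    out <- death_trial(st, 1)
    expect_equal(sum(out$grid == 0), 1)
  })
  # fully empty and fully occupied lattices are absorbing for the birth trial
  empty <- lvlattice:::new_lattice_state(matrix(0L, 5, 5))
  withr::with_seed(2, {
    for (k in 1:10) {
      expect_identical(birth_trial(empty, 1, "local")$grid, empty$grid)
      expect_identical(birth_trial(st, 1, "local")$grid, st$grid)
    }
  })
  # single parent with birth probability 1: when the parent is drawn first,
  # one von Neumann neighbour becomes the same species
  one <- matrix(0L, 3, 3)
  one[2, 2] <- 1L
  st1 <- lvlattice:::new_lattice_state(one)
  withr::with_seed(3, {
    grown <- st1
    while (sum(grown$grid) == 1) grown <- birth_trial(grown, 1, "local")
    expect_equal(sum(grown$grid == 1), 2)
    new_cell <- which(grown$grid == 1 & one == 0)
    expect_true(new_cell %in% c(4, 6, 2, 8))  # the 4 neighbours of centre
  })
})

test_that("one Monte Carlo step thins a full lattice by the escape probability", {
  # every cell survives the L^2 uniform death draws with probability
  # (1 - m/L^2)^(L^2) ~ exp(-m); births are off
  solo <- one_species(1)
  L <- 50
  for (m in c(1, 0.3)) {
    fracs <- vapply(1:60, function(s) {
      st <- lvlattice:::new_lattice_state(matrix(1L, L, L))
      out <- mc_step(st, birth = 0, mortality = m, mode = "local",
                     n_steps = 1, seed = 1e6 * m + s)
      mean(out$grid > 0)
    }, numeric(1))
    expect_lt(abs(mean(fracs) - exp(-m)), 0.015)
  }
})

test_that("mortality-free dynamics never lose individuals", {
  solo <- one_species(0)
  cfg <- sim_config(L = 40, steps = 50, mode = "local", seed = 9,
                    initial_occupancy = 0.1, record_every = 1)
  sim <- run_simulation(cfg, solo, birth = 0.8)
  expect_true(all(diff(sim$series$x_1) >= 0))
})

test_that("densities are conserved and runs are reproducible bit-for-bit", {
  comm <- tiny_community(5)
  cfg <- sim_config(L = 60, steps = 200, mode = "local", P = 15, seed = 77,
                    record_every = 20)
  sim1 <- run_simulation(cfg, comm)
  sim2 <- run_simulation(cfg, comm)
  expect_identical(sim1$series, sim2$series)
  expect_identical(sim1$state$grid, sim2$state$grid)
  xs <- as.matrix(sim1$series[, paste0("x_", 1:5)])
  expect_true(all(rowSums(xs) + sim1$series$e == 1))
  expect_true(all(sim1$state$grid %in% 0:5))
  # a different seed gives a different trajectory
  cfg$seed <- 78L
  expect_false(identical(run_simulation(cfg, comm)$series, sim1$series))
  # steps = 0: a single record equal to the initial densities
  cfg0 <- sim_config(L = 60, steps = 0, P = 15, seed = 1,
                     initial_occupancy = 0.3)
  sim0 <- run_simulation(cfg0, comm)
  expect_equal(nrow(sim0$series), 1)
  expect_equal(sum(sim0$series[paste0("x_", 1:5)]), floor(0.3 * 60^2) / 60^2)
})

test_that("sub-threshold single-species runs go extinct", {
  solo <- one_species(0.3)
  cfg <- sim_config(L = 100, steps = 2000, mode = "local", seed = 13,
                    record_every = 500)
  sim <- run_simulation(cfg, solo, birth = 0.45)
  expect_equal(tail(sim$series$x_1, 1), 0)
  expect_equal(richness(sim$state), 0L)
})

test_that("richness counts species with at least one individual", {
  expect_equal(richness(matrix(0L, 4, 4)), 0L)
  g <- matrix(0L, 4, 4)
  g[1, 1] <- 2L
  g[3, 2] <- 7L
  expect_equal(richness(g), 2L)
  expect_equal(richness(matrix(1L, 4, 4)), 1L)
  # per-record richness on a density series
  df <- tibble::tibble(step = 0:1, x_1 = c(0.1, 0), x_2 = c(0.2, 0.3),
                       e = c(0.7, 0.7))
  expect_equal(richness(df), c(2L, 1L))
})

test_that("adjacency statistics classify all 2 L^2 neighbour pairs", {
  expect_equal(adjacency_stats(matrix(0L, 10, 10))$empty_empty_pairs, 200)
  # two-species checkerboard: every pair is cross-species
  L <- 6
  cb <- outer(1:L, 1:L, function(r, c) 1L + (r + c) %% 2L)
  ac <- adjacency_stats(cb)
  expect_equal(ac$cross_species_pairs, 2 * L^2)
  expect_equal(ac$same_species_pairs + ac$species_empty_pairs +
                 ac$empty_empty_pairs, 0)
  full <- adjacency_stats(matrix(2L, 8, 8))
  expect_equal(full$same_species_pairs, 2 * 64)
  # mixed random grid: classes partition the pair set
  withr::with_seed(4, {
    g <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
    a <- adjacency_stats(g)
    expect_equal(sum(as.numeric(a)), 2 * 144)
  })
})

test_that("threshold estimation brackets the transition and handles edge cases", {
  # mortality 0: persistence at every b, so the scan cannot bracket
  expect_error(
    estimate_threshold("local", 0, L = 30, steps = 50,
                       b_grid = c(0.1, 0.2), replicates = 1, seed = 1),
    "bracket")
  # far sub-threshold grid: extinction everywhere
  expect_error(
    estimate_threshold("local", 0.9, L = 30, steps = 500,
                       b_grid = c(0.05, 0.1), replicates = 1, seed = 1),
    "bracket")
  expect_error(
    estimate_threshold("local", 0.3, b_grid = c(0.5, 0.4)), "ascending")
  # a coarse scan brackets the known local transition and survival is
  # monotone across well-separated birth probabilities
  th <- estimate_threshold("local", 0.3, L = 60, steps = 1500,
                           b_grid = seq(0.40, 0.70, by = 0.05),
                           replicates = 3, seed = 42)
  expect_gte(th$estimate, 0.45)
  expect_lte(th$estimate, 0.60)
  expect_true(all(diff(tidy(th)$frac) >= 0))
  expect_equal(glance(th)$mode, "local")
})
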