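test_that("mean-field right-hand side matches direct arithmetic", {
  # fixed points
  expect_equal(mf_rhs(0, 0.6, 0.3), 0)
  expect_equal(mf_rhs(0.5, 0.6, 0.3), 0)  # x* = 1 - m/b
  # off-equilibrium: x (b e - m) = 0.25 (0.6 * 0.75 - 0.3)
  expect_equal(mf_rhs(0.25, 0.6, 0.3), 0.0375)
  # multi-species: shared empty pool couples the equations
  expect_equal(mf_rhs(c(0.2, 0.3), c(0.6, 0.5), c(0.3, 0.3)),
               c(0.2 * (0.6 * 0.5 - 0.3), 0.3 * (0.5 * 0.5 - 0.3)))
  expect_error(mf_rhs(c(-0.1, 0.2), 0.6, 0.3), "simplex")
  expect_error(mf_rhs(c(0.6, 0.6), 0.6, 0.3), "simplex")
})

test_that("single-species trajectory matches the closed-form logistic", {
  tr <- integrate_mf(0.01, birth = 0.6, mortality = 0.3, T = 200, dt = 0.01,
                     record_every = 100)
  expect_equal(tr$x_1, logistic_closed_form(tr$t, 0.01, 0.6, 0.3),
               tolerance = 1e-6)
  expect_equal(tail(tr$x_1, 1), 0.5, tolerance = 1e-4)
  # zero start stays zero
  tr0 <- integrate_mf(0, 0.6, 0.3, T = 10)
  expect_true(all(tr0$x_1 == 0))
  expect_error(integrate_mf(0.1, 0.6, 0.3, T = 1, dt = 0), "dt")
})

test_that("trajectories stay on the simplex and exclude the smaller-K species", {
  withr::with_seed(11, {
    for (k in 1:5) {
      N <- sample(2:5, 1)
      b <- runif(N, 0.4, 0.9)
      m <- runif(N, 0.1, 0.35)
      x0 <- runif(N, 0, 1 / (2 * N))
      tr <- integrate_mf(x0, b, m, T = 3000, dt = 0.05, record_every = 1000)
      xs <- as.matrix(tr[, paste0("x_", seq_len(N))])
      expect_true(all(xs >= 0))
      expect_true(all(rowSums(xs) <= 1 + 1e-9))
      expect_true(all(abs(rowSums(xs) + tr$e - 1) < 1e-9))
      K <- pmax(0, 1 - m / b)
      if (max(K) > 0 && sum(abs(K - max(K)) < 0.02) == 1) {
        final <- xs[nrow(xs), ]
        # generic competitive exclusion: only the largest-K species persists
        expect_equal(sum(final > 1e-6), 1L)
        expect_gt(final[which.max(K)], 1e-6)
      }
    }
  })
})

test_that("two-species reduction gives the documented Lotka-Volterra parameters", {
  lv <- lv_mapping(0.6, 0.3, 0.55, 0.3)
  expect_equal(lv$R, c(0.3, 0.25))
  expect_equal(lv$K, c(0.5, 0.25 / 0.55))
  # K coincides with the single-species equilibrium for any valid rates
  withr::with_seed(3, {
    b <- runif(20, 0.05, 1)
    m <- runif(20, 0, 1)
    expect_equal(pmax(0, lv_mapping(b[1], m[1], b[2], m[2])$K[1]),
                 single_species_equilibrium(b[1], m[1]))
    expect_equal(pmax(0, (b - m) / b)[b > m],
                 single_species_equilibrium(b, m)[b > m])
  })
  expect_equal(single_species_equilibrium(0.6, 0.3), 0.5)
  expect_equal(single_species_equilibrium(0.3, 0.3), 0)
  expect_equal(single_species_equilibrium(0.54, 0.5), 1 - 0.5 / 0.54)
  expect_error(single_species_equilibrium(0, 0.3), "positive")
})

test_that("equilibrium classification covers the four stationary classes", {
  expect_identical(classify_equilibrium(0.2, 0.3, 0.2, 0.3), "both_extinct")
  expect_identical(classify_equilibrium(0.6, 0.3, 0.2, 0.3), "species1_only")
  expect_identical(classify_equilibrium(0.2, 0.3, 0.6, 0.3), "species2_only")
  expect_identical(classify_equilibrium(0.6, 0.3, 0.55, 0.3), "species1_only")
  expect_identical(classify_equilibrium(0.55, 0.3, 0.6, 0.3), "species2_only")
  expect_identical(classify_equilibrium(0.6, 0.3, 0.6, 0.3), "degenerate")
  # community interface at a fixed nutrient level: above the pivot the
  # larger-b_max species carries the larger K and wins
  comm <- default_community(10)
  expect_identical(classify_community_pair(comm, 1, 10, 15.5),
                   "species1_only")
  expect_identical(classify_community_pair(comm, 1, 10, 14.0),
                   "species2_only")
})

test_that("classification agrees with an independent adaptive ODE solve", {
  rhs <- function(t, x, p) {
    list(pmax(x, 0) * (p$b * (1 - sum(pmax(x, 0))) - p$m))
  }
  withr::with_seed(23, {
    for (k in 1:20) {
      b <- runif(2, 0.1, 0.9)
      m <- runif(2, 0.1, 0.6)
      # near-degenerate draws (|R| or |K1 - K2| tiny) take unboundedly long
      # to resolve by integration; they are the documented "degenerate" edge
      if (any(abs(b - m) < 0.02)) next
      if (abs(diff(pmax(0, 1 - m / b))) < 0.05) next
      cls <- classify_equilibrium(b[1], m[1], b[2], m[2])
      sol <- deSolve::ode(c(0.1, 0.1), times = c(0, 2e4), rhs,
                          list(b = b, m = m), method = "lsoda")
      final <- pmax(sol[nrow(sol), 2:3], 0)
      expected <- switch(cls,
        both_extinct = c(FALSE, FALSE),
        species1_only = c(TRUE, FALSE),
        species2_only = c(FALSE, TRUE))
      expect_identical(unname(final > 1e-4), expected,
                       info = sprintf("b=%.3f/%.3f m=%.3f/%.3f", b[1], b[2],
                                      m[1], m[2]))
    }
  })
})
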