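# Shared fixtures, all generated in code.

# a small default-construction community for cheap multi-species runs
tiny_community <- function(N = 3, mortality = 0.3) {
  default_community(N, mortality = mortality)
}

# one-species community whose birth comes from a constant-b override
one_species <- function(mortality) {
  lvlattice:::single_species_community(mortality)
}

# closed-form logistic solution of dx/dt = x (b (1 - x) - m)
logistic_closed_form <- function(t, x0, b, m) {
  K <- 1 - m / b
  R <- b - m
  K / (1 + (K / x0 - 1) * exp(-R * t))
}
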