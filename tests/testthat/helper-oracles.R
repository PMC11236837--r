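# Independent oracles used across tests: kept deliberately naive so they
# share no code path with the package internals they check.

# All achievable means of I responses by full K^I tuple enumeration.
brute_force_means <- function(values, I, digits = 9) {
  tuples <- do.call(expand.grid, rep(list(values), I))
  sort(unique(round(rowMeans(tuples), digits)))
}

# Nearest-element snapping by explicit distance minimisation (ties -> smaller).
naive_snap <- function(x, lattice) {
  vapply(x, function(v) {
    d <- abs(lattice - v)
    lattice[which(d == min(d))][1L]
  }, numeric(1))
}

# Random composition with a given total.
random_composition <- function(D, kappa) {
  w <- stats::rexp(D) + 0.05
  composition(kappa * w / sum(w), kappa)
}
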