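# Shared fixtures for the test suite (built in code, no data files).

# The strongly non-normal 2x2 stable-but-reactive community and its weak
# counterpart: upper-triangular Jacobians with one-way interaction.
reactive_2x2 <- function() matrix(c(-1, 0, 3, -1), 2)
nonreactive_2x2 <- function() matrix(c(-1, 0, 0.3, -1), 2)

expect_rel <- function(measured, expected, tol) {
  expect_lt(abs(measured - expected) / abs(expected), tol)
}

# mean off-diagonal statistics over an ensemble of community matrices
ensemble_mean_moments <- function(spec, n) {
  ms <- generate_ensemble(spec, n)
  st <- lapply(ms, function(m) empirical_moments(m$values))
  list(E = mean(vapply(st, `[[`, numeric(1), "E")),
       V = mean(vapply(st, `[[`, numeric(1), "V")),
       rho = mean(vapply(st, `[[`, numeric(1), "rho")))
}
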