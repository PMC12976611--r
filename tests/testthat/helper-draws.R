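# Random valid parameter draws for property-style tests.  Wall
# coefficients are kept in a moderate range so that nonlinear-oracle
# comparisons stay inside the invertible region of the constitutive map.
random_params <- function(n_draws, moderate_wall = TRUE) {
  lapply(seq_len(n_draws), function(i) {
    phi <- runif(1, 0, 0.3)
    scale <- if (moderate_wall) 0.05 else 1
    validate_params(list(
      e1 = runif(1, 0, 1) * scale, e2 = runif(1, 0, 1) * scale,
      e3 = runif(1, 0, 1) * scale, e4 = runif(1, 0, 1) * scale,
      e5 = runif(1, 0, 1) * scale,
      Omega = runif(1, 0, 1.5), G1 = runif(1, -2, 2), G2 = runif(1, -2, 2),
      S1 = runif(1, 0, 1), S2 = runif(1, 0.1, 1),
      Rn = runif(1, 0.2, 2), Pr = runif(1, 0.5, 3),
      eps = runif(1, 0.1, min(0.4, 0.9 - phi)), phi = phi,
      We = runif(1, 0, 0.3), alpha = runif(1, 0, 0.3),
      n = runif(1, 0.2, 1.2)))
  })
}

# Parameter set with one field replaced (re-validated).
tweak <- function(params, ...) {
  validate_params(utils::modifyList(unclass(params), list(...)))
}
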