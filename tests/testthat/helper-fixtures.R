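# Shared fixtures: gentle, well-conditioned parameter sets and small grids
# so unit tests stay fast; acceptance tests build their own full-size grids.

test_kp <- function() kernel_params(l = 0.1, max = 4, slope = 8, loc = 3,
                                    decay = 0.5)
test_mp <- function() mean_params(r0 = 3, s0 = 8)

test_hp <- function(noise = 0.2) rdf_hyperparams(test_mp(), test_kp(), noise)

# small argon-like measurement: coarse window keeps d modest
argon_measurement <- function(seed = 1, noise_var = 0.04, delta_q = 0.1,
                              q_max = 15) {
  truth <- synthetic_rdf("argon")
  sq <- rdf_to_sq(truth)
  corrupt_measurement(sq, delta_q, 0.5, q_max, noise_var, seed = seed)
}

fast_control <- function(...) gp_control(r_step = 0.05, ...)

# dense multivariate-normal log density via determinant()/solve(): the
# independent oracle path for the log marginal likelihood
mvn_logpdf <- function(y, mu, C) {
  d <- length(y)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  r <- y - mu
  -0.5 * drop(crossprod(r, solve(C, r))) - 0.5 * ld - d / 2 * log(2 * pi)
}
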