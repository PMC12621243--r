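test_that("dataset constructor validates and carries metadata", {
  tb <- tibble::tibble(q = c(1, 2, 3), S = c(1.1, 0.9, 1.0))
  d <- scattering_data(tb, density = 0.02, temperature = 85)
  expect_equal(nrow(d), 3L)
  expect_equal(attr(d, "density"), 0.02)
  expect_equal(attr(d, "temperature"), 85)
  expect_error(scattering_data(tb[1, ], 0.02), "at least 2")
  expect_error(scattering_data(tibble::tibble(q = c(2, 1), S = c(1, 1)), 0.02),
               "increasing")
  expect_error(scattering_data(tb, -1), "positive")
  expect_error(scattering_data(dplyr::mutate(tb, S = c(1, NA, 1)), 0.02),
               "finite")
  empty <- scattering_data(tibble::tibble(q = numeric(), S = numeric()), 0.02)
  expect_equal(nrow(empty), 0L)
})

test_that("log marginal likelihood reproduces closed forms", {
  # single point, zero prior covariance, unit noise, zero residual
  expect_equal(lml_core(0, matrix(1, 1, 1)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # residuals only enter through Y - mu: shifting both leaves them unchanged
  C <- diag(2, 3) + 0.5
  y <- c(0.3, -0.2, 0.1)
  expect_equal(lml_core(y, C), lml_core((y + 5) - 5, C), tolerance = 1e-10)
  # permutation invariance of the data ordering
  p <- c(3, 1, 2)
  expect_equal(lml_core(y[p], C[p, p]), lml_core(y, C), tolerance = 1e-10)
})

test_that("log marginal likelihood matches a dense multivariate-normal oracle", {
  d15 <- argon_measurement(seed = 5, delta_q = 1, q_max = 15)  # 15 points
  hp <- test_hp()
  ctrl <- fast_control()
  got <- log_marginal_likelihood(d15, hp, ctrl)
  # oracle: prior kernel transformed by the dense operator route, then the
  # plain determinant/solve Gaussian log density
  r <- seq(0, ctrl$r_max, by = ctrl$r_step)
  inv <- rft_operator(r, d15$q, attr(d15, "density"), "inverse")
  Kqq <- transform_kernel(kernel_gram(r, r, kp = hp$kernel), inv)
  mu_q <- mean_structure_factor(hp$mean, inv)
  oracle <- mvn_logpdf(d15$S, mu_q, Kqq + diag(hp$noise^2, nrow(d15)))
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("an empty dataset returns the prior", {
  hp <- test_hp()
  ctrl <- fast_control()
  empty <- scattering_data(tibble::tibble(q = numeric(), S = numeric()),
                           density = 0.02125)
  rq <- seq(0, 8, by = 0.25)
  post <- posterior_r(empty, rq, hp = hp, control = ctrl)
  expect_equal(post$mean, mean_rdf(rq, hp$mean), tolerance = 1e-12)
  expect_equal(post$cov, kernel_gram(rq, rq, kp = hp$kernel), tolerance = 1e-12)
  qq <- seq(0.5, 10, by = 0.5)
  postq <- posterior_q(empty, qq, hp = hp, include_noise = FALSE,
                       control = ctrl)
  r <- seq(0, ctrl$r_max, by = ctrl$r_step)
  inv <- rft_operator(r, qq, 0.02125, "inverse")
  expect_equal(postq$mean, mean_structure_factor(hp$mean, inv),
               tolerance = 1e-10)
})

test_that("near-noiseless conditioning interpolates the observations", {
  m <- argon_measurement(seed = 2, noise_var = 0, delta_q = 0.5)
  hp <- test_hp(noise = 1e-8)
  ctrl <- fast_control()
  post <- posterior_q(m, m$q, hp = hp, include_noise = FALSE, control = ctrl)
  expect_lt(max(abs(post$mean - m$S)), 1e-4)
  prior <- posterior_q(scattering_data(m[0, ], attr(m, "density")), m$q,
                       hp = hp, include_noise = FALSE, control = ctrl)
  # variance collapse where the prior carries appreciable variance (at high
  # q the prior variance itself is already at roundoff level)
  pv <- diag(prior$cov)
  informative <- pv >= 1e-4 * max(pv)
  expect_lt(max(diag(post$cov)[informative] / pv[informative]), 1e-6)
})

test_that("posterior matches brute-force joint-Gaussian block conditioning", {
  m <- argon_measurement(seed = 4, delta_q = 0.7, q_max = 13.9)  # 20 points
  expect_equal(nrow(m), 20L)
  hp <- test_hp()
  ctrl <- fast_control()
  q_star <- seq(0.8, 13.8, by = 1)
  got <- posterior_q(m, q_star, hp = hp, include_noise = FALSE,
                     control = ctrl)
  # oracle: build the full (d + m) joint covariance by the dense operator
  # route and condition by explicit block inversion
  r <- seq(0, ctrl$r_max, by = ctrl$r_step)
  K <- kernel_gram(r, r, kp = hp$kernel)
  At <- rft_operator(r, m$q, attr(m, "density"), "inverse")$weights
  As <- rft_operator(r, q_star, attr(m, "density"), "inverse")$weights
  Ktt <- At %*% K %*% t(At) + diag(hp$noise^2, nrow(m))
  Kst <- As %*% K %*% t(At)
  Kss <- As %*% K %*% t(As)
  mu_t <- 1 + drop(At %*% (mean_rdf(r, hp$mean) - 1))
  mu_s <- 1 + drop(As %*% (mean_rdf(r, hp$mean) - 1))
  mean_oracle <- mu_s + drop(Kst %*% solve(Ktt, m$S - mu_t))
  cov_oracle <- Kss - Kst %*% solve(Ktt, t(Kst))
  expect_equal(got$mean, mean_oracle, tolerance = 1e-8)
  expect_equal(got$cov, (cov_oracle + t(cov_oracle)) / 2, tolerance = 1e-8)
})

test_that("posterior sampling is seeded, exact for zero covariance, unbiased", {
  hp <- test_hp()
  grid <- seq(1, 4, by = 0.1)
  post <- structure(list(space = "r", grid = grid,
                         mean = sin(grid), cov = diag(0, length(grid)),
                         noise_free = FALSE, hyperparams = hp, density = 0.02),
                    class = "rdf_posterior")
  s <- sample_posterior(post, 5, seed = 9)
  expect_equal(unname(s), matrix(sin(grid), 5, length(grid), byrow = TRUE))
  post$cov <- 0.2 * exp(-outer(grid, grid, "-")^2)
  s1 <- sample_posterior(post, 100, seed = 3)
  s2 <- sample_posterior(post, 100, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_posterior(post, 100, seed = 4)))
  # CLT bound on the Monte-Carlo mean
  n <- 20000
  sm <- colMeans(sample_posterior(post, n, seed = 1))
  sdv <- sqrt(diag(post$cov))
  frac_in <- mean(abs(sm - post$mean) <= 4 * sdv / sqrt(n))
  expect_gte(frac_in, 0.99)
})

test_that("noise-free posterior nests inside the noisy predictive band", {
  m <- argon_measurement(seed = 6, delta_q = 0.25)
  hp <- test_hp(noise = 0.2)
  ctrl <- fast_control()
  noisy <- posterior_q(m, m$q, hp = hp, control = ctrl)   # include_noise TRUE
  nf <- noise_free_posterior(m, m$q, hp = hp, space = "q", control = ctrl)
  expect_true(nf$noise_free)
  expect_true(all(diag(nf$cov) < diag(noisy$cov)))
  expect_true(all(diag(nf$cov) <= diag(noisy$cov) - hp$noise^2 + 1e-12))
  # with omega = 0 the two coincide
  hp0 <- test_hp(noise = 0)
  a <- posterior_q(m, m$q, hp = hp0, control = ctrl)
  b <- noise_free_posterior(m, m$q, hp = hp0, space = "q", control = ctrl)
  expect_equal(a$mean, b$mean)
  expect_equal(a$cov, b$cov)
})

test_that("conditioning only ever shrinks the prior covariance", {
  m <- argon_measurement(seed = 8, delta_q = 0.5)
  hp <- test_hp()
  ctrl <- fast_control()
  rq <- seq(0, 10, by = 0.25)
  post <- posterior_r(m, rq, hp = hp, control = ctrl)
  prior <- kernel_gram(rq, rq, kp = hp$kernel)
  ev <- eigen(prior - post$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(diag(prior)))
})

test_that("r-space posterior relaxes to the mean at both boundaries", {
  m <- argon_measurement(seed = 1, delta_q = 0.1)
  hp <- test_hp()
  ctrl <- fast_control()
  rq <- c(seq(0, 1, by = 0.25), seq(23, 25, by = 0.5))
  post <- posterior_r(m, rq, hp = hp, control = ctrl)
  sdv <- sqrt(pmax(diag(post$cov), 0))
  i <- length(rq)
  expect_lte(abs(post$mean[i] - 1), 3 * sdv[i] + 1e-6)
  # where the width function vanishes the posterior pins to the prior mean
  expect_lt(max(abs(post$mean[rq <= 1] - mean_rdf(rq[rq <= 1], hp$mean))),
            1e-6)
})

test_that("type-II ML never degrades the initial log marginal likelihood", {
  m <- argon_measurement(seed = 3, delta_q = 0.25)
  ctrl <- fast_control(maxit = 5)
  init <- test_hp(noise = 0.25)
  fit <- fit_rdf_gp(m, init = init, n_restarts = 1, seed = 1, control = ctrl)
  expect_gte(fit$lml, fit$lml_init - 1e-8)
  expect_s3_class(fit$trace, "tbl_df")
  expect_gt(nrow(fit$trace), 0)
  expect_equal(fit$lml, max(fit$trace$lml))
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$param[1:8], c("r0", "s0", "l", "max", "slope", "loc",
                                "decay", "omega"))
  expect_equal(glance(fit)$d, nrow(m))
})

test_that("the noise level is recovered from pure-noise data", {
  hp <- test_hp(noise = 0.2)
  ctrl <- fast_control(maxit = 40)
  q <- seq(0.05, 15, length.out = 300)
  r <- seq(0, ctrl$r_max, by = ctrl$r_step)
  inv <- rft_operator(r, q, 0.02125, "inverse")
  mu_q <- mean_structure_factor(hp$mean, inv)
  Y <- mu_q + withr::with_seed(77, rnorm(300, 0, 0.2))
  dat <- scattering_data(tibble::tibble(q = q, S = Y), density = 0.02125)
  # freeze everything except omega at the generating values
  th <- as_theta(hp)
  bounds <- default_bounds()
  bounds$lower <- th; bounds$upper <- th
  bounds$lower[bounds$param == "omega"] <- 1e-4
  bounds$upper[bounds$param == "omega"] <- 1
  fit <- fit_rdf_gp(dat, init = hp, bounds = bounds, n_restarts = 1,
                    seed = 1, control = ctrl)
  omega_hat <- fit$hyperparams$noise
  expect_gt(omega_hat, 0.15)
  expect_lt(omega_hat, 0.25)
})

test_that("a supplied per-point noise column replaces the scalar noise", {
  m <- argon_measurement(seed = 9, delta_q = 0.5)
  hp <- test_hp(noise = 0.2)
  ctrl <- fast_control()
  m_het <- m
  m_het$sd <- rep(0.2, nrow(m))
  het <- scattering_data(m_het, attr(m, "density"))
  expect_equal(log_marginal_likelihood(het, hp, ctrl),
               log_marginal_likelihood(m, hp, ctrl), tolerance = 1e-10)
  # a different diagonal changes the answer
  m_het$sd <- rep(0.05, nrow(m))
  het2 <- scattering_data(m_het, attr(m, "density"))
  expect_false(isTRUE(all.equal(log_marginal_likelihood(het2, hp, ctrl),
                                log_marginal_likelihood(m, hp, ctrl))))
})
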