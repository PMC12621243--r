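test_that("parameter constructors validate", {
  expect_error(kernel_params(-1, 1, 2, 1, 0.5), "finite and > 0")
  expect_error(kernel_params(0.1, 1, 0.4, 1, 0.5), "slope must exceed decay")
  expect_error(mean_params(-1, 2), "positive")
  expect_error(mean_params(2, 2, bonded = data.frame(h = 1, r = -1, s = 0.1)),
               "positive")
  expect_error(mean_params(2, 2, bonded = data.frame(a = 1)), "columns")
})

test_that("width function obeys its algebraic anchors", {
  kp <- test_kp()
  expect_equal(width_sigma(kp$loc, kp), kp$max / 2, tolerance = 1e-12)
  # exponential-decay limit far beyond the sigmoid
  far <- kp$loc + 200 / kp$decay
  expect_lte(width_sigma(far, kp), kp$max * 1e-80)
  # exact value at r = 0 from the sigmoid tail (suppressed by the factor
  # exp(-slope * loc) relative to the peak, carrying the exp(decay * loc)
  # normalization of the width formula)
  expect_equal(width_sigma(0, kp),
               kp$max * exp(kp$decay * kp$loc) / (1 + exp(kp$slope * kp$loc)),
               tolerance = 1e-12)
  # no overflow across the symmetrization range
  expect_true(all(is.finite(width_sigma(seq(-100, 100, by = 0.5), kp))))
})

test_that("width function decreases monotonically beyond its peak", {
  kp <- kernel_params(l = 0.1, max = 4, slope = 8, loc = 1.5, decay = 0.4)
  r <- seq(5, 25, by = 0.01)
  s <- width_sigma(r, kp)
  expect_true(all(diff(s) < 0))
})

test_that("Gibbs kernel collapses correctly on the diagonal and is symmetric", {
  kp <- test_kp()
  r <- c(0.5, 2, 3, 4.5, 7)
  for (x in r) {
    expect_equal(gibbs_kernel(x, x, kp), width_sigma(x, kp)^2 * sqrt(kp$l),
                 tolerance = 1e-14)
  }
  for (x in r) for (y in r) {
    expect_identical(gibbs_kernel(x, y, kp), gibbs_kernel(y, x, kp))
  }
})

test_that("Gibbs and symmetrized Gram matrices are PSD to jitter tolerance", {
  kp <- test_kp()
  pts <- withr::with_seed(11, sort(runif(50, 0, 20)))
  G1 <- outer(pts, pts, gibbs_kernel, kp = kp)
  ev1 <- eigen(G1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev1), -1e-8 * max(diag(G1)))
  G2 <- kernel_gram(pts, pts, kp = kp)
  ev2 <- eigen(G2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev2), -1e-8 * max(diag(G2)))
})

test_that("symmetrized kernel is even about r = 0 by construction", {
  kp <- test_kp()
  expect_equal(gibbs_kernel_sym(0, 2.3, kp), 2 * gibbs_kernel(0, 2.3, kp),
               tolerance = 1e-14)
  probes <- expand.grid(r = c(0.3, 1.1, 2.5, 4), rp = c(0.5, 1.7, 3.2))
  for (i in seq_len(nrow(probes))) {
    d <- abs(gibbs_kernel_sym(-probes$r[i], probes$rp[i], kp) -
             gibbs_kernel_sym(probes$r[i], probes$rp[i], kp))
    expect_lt(d, 1e-12)
  }
})

test_that("kernel_gram is the exact transpose average of the two-term sum", {
  kp <- test_kp()
  r <- seq(0, 10, by = 0.25)
  V <- outer(r, r, gibbs_kernel_sym, kp = kp)
  expect_equal(kernel_gram(r, r, kp = kp), (V + t(V)) / 2, tolerance = 1e-13)
})

test_that("mean components hit their closed-form anchors", {
  mp <- test_mp()
  expect_equal(mean_nonbonded(mp$r0, mp), 0.5)
  expect_equal(mean_nonbonded(mp$r0 + 100 / mp$s0, mp), 1, tolerance = 1e-40)
  expect_equal(mean_nonbonded(0, mp), 1 / (1 + exp(mp$s0 * mp$r0)))
  expect_equal(mean_bonded(c(1, 2), mp), c(0, 0))
  mpb <- mean_params(3, 8, bonded = data.frame(h = 2, r = 1.6, s = 0.08))
  expect_equal(mean_bonded(1.6, mpb), 2 / (0.08 * sqrt(2 * pi)))
  expect_equal(mean_rdf(mp$r0, mp), 0.5)
  expect_equal(mean_rdf(mp$r0 + 100 / mp$s0, mp), 1, tolerance = 1e-12)
})

test_that("argon-like mean rises monotonically from 0 to 1", {
  mp <- test_mp()
  r <- seq(0, 25, by = 0.01)
  m <- mean_rdf(r, mp)
  expect_true(all(diff(m) >= 0))
  expect_lt(m[1], 1e-3)
  expect_equal(m[length(m)], 1, tolerance = 1e-12)
})

test_that("momentum-space mean matches a quadrature oracle and is linear", {
  rho <- 0.0334
  r <- seq(0, 25, by = 0.005)
  q_probe <- c(1, 5, 10)
  op <- rft_operator(r, q_probe, rho, "inverse")
  # a single bonded Gaussian term against adaptive quadrature
  h <- 0.9; rb <- 1.6; sb <- 0.08
  peak <- h * dnorm(r, rb, sb)
  got <- apply_rft(op, peak)
  oracle <- vapply(q_probe, function(qq) {
    4 * pi * rho * stats::integrate(function(x)
      h * dnorm(x, rb, sb) * sinc_qr(rep(qq, length(x)), x) * x^2,
      0, 25, rel.tol = 1e-12)$value
  }, numeric(1))
  expect_lt(max(abs(got - oracle) / abs(oracle)), 1e-3)
  # linearity across bonded-peak decompositions
  mp0 <- mean_params(3, 8)
  mp1 <- mean_params(3, 8, bonded = data.frame(h = 1, r = 1.0, s = 0.05))
  mp2 <- mean_params(3, 8, bonded = data.frame(h = 0.5, r = 1.6, s = 0.08))
  mp12 <- mean_params(3, 8, bonded = data.frame(h = c(1, 0.5),
                                                r = c(1.0, 1.6),
                                                s = c(0.05, 0.08)))
  lhs <- mean_structure_factor(mp12, op)
  rhs <- mean_structure_factor(mp1, op) + mean_structure_factor(mp2, op) -
    mean_structure_factor(mp0, op)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_error(mean_structure_factor(mp0, rft_operator(q_probe, r[-1], rho,
                                                       "forward")),
               "inverse-direction")
})

test_that("q-space transformed prior covariance stays symmetric PSD", {
  kp <- test_kp()
  r <- seq(0, 20, by = 0.02)
  q <- seq(0.2, 12, by = 0.2)
  inv <- rft_operator(r, q, 0.02125, "inverse")
  Kq <- transform_kernel(kernel_gram(r, r, kp = kp), inv)
  expect_equal(Kq, t(Kq))
  ev <- eigen(Kq, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(diag(Kq)))
})

test_that("mean deviation from 1 has a negligible far tail", {
  mpb <- mean_params(3, 8, bonded = data.frame(h = 1, r = 1.6, s = 0.08))
  expect_lt(abs(mean_rdf(25, mpb) - 1) * 25^2, 1e-10)
})
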