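#' Construct a scattering dataset
#'
#' Bundles structure-factor observations with the metadata the GP needs.
#' Column `q` is the momentum transfer (1/angstrom, strictly increasing),
#' `S` the dimensionless structure factor, and an optional `sd` column gives
#' per-point observation noise standard deviations (a fixed heteroscedastic
#' diagonal that then replaces the scalar noise omega^2 I).
#'
#' An empty table (0 rows) is accepted solely so the posterior functions can
#' return the prior; fitting requires at least 2 points.
#'
#' @param x Data frame with numeric columns `q`, `S` and optionally `sd`.
#' @param density Atomic number density rho (atoms/angstrom^3), positive.
#' @param temperature Optional temperature in kelvin (metadata only).
#' @return An object of class `scattering_data` (a tibble with attributes).
#' @export
scattering_data <- function(x, density, temperature = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("q", "S") %in% names(x))) {
    stop("scattering_data: need columns q and S", call. = FALSE)
  }
  keep <- intersect(c("q", "S", "sd"), names(x))
  x <- x[keep]
  if (nrow(x) == 1L) {
    stop("scattering_data: need at least 2 observations (or 0 for a prior-only dataset)",
         call. = FALSE)
  }
  if (nrow(x) > 0L) {
    check_momentum_grid(x$q)
    if (anyNA(x$S) || any(!is.finite(x$S))) {
      stop("scattering_data: S values must be finite", call. = FALSE)
    }
    if ("sd" %in% names(x) && (anyNA(x$sd) || any(x$sd <= 0))) {
      stop("scattering_data: sd values must be positive", call. = FALSE)
    }
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("scattering_data: density must be a single positive number",
         call. = FALSE)
  }
  structure(x, density = density, temperature = temperature,
            class = c("scattering_data", class(x)))
}

#' @export
print.scattering_data <- function(x, ...) {
  cat(sprintf("<scattering_data> d = %d observations, rho = %g atoms/A^3%s%s\n",
              nrow(x), attr(x, "density"),
              if (!is.null(attr(x, "temperature")))
                sprintf(", T = %g K", attr(x, "temperature")) else "",
              if ("sd" %in% names(x)) ", per-point noise sd" else ""))
  NextMethod()
}

#' Full hyperparameter set of the nonstationary GP
#'
#' Combines the mean parameters, kernel parameters and the homoscedastic
#' observation-noise standard deviation omega. For a simple liquid with no
#' bonded peaks the parameter vector is
#' `[r0, s0, l, max, slope, loc, decay, omega]`.
#'
#' @param mean A [mean_params()] object.
#' @param kernel A [kernel_params()] object.
#' @param noise Observation noise sd omega (dimensionless), `>= 0`.
#' @return An object of class `rdf_hyperparams`.
#' @export
rdf_hyperparams <- function(mean, kernel, noise) {
  stopifnot(inherits(mean, "mean_params"), inherits(kernel, "kernel_params"))
  if (!is.numeric(noise) || length(noise) != 1L || !is.finite(noise) ||
      noise < 0) {
    stop("rdf_hyperparams: noise must be a single number >= 0", call. = FALSE)
  }
  structure(list(mean = mean, kernel = kernel, noise = noise),
            class = "rdf_hyperparams")
}

#' @export
print.rdf_hyperparams <- function(x, ...) {
  v <- as_theta(x)
  cat("<rdf_hyperparams>\n")
  print(round(v, 6))
  invisible(x)
}

#' Numerical controls for GP fitting
#'
#' @param r_max Extent of the internal r quadrature grid (angstrom) used for
#'   all kernel/mean transforms during fitting. The prior's exponential decay
#'   makes the tail beyond 25 angstrom negligible for valid parameters.
#' @param r_step Step of the internal r grid (angstrom). 0.02 resolves
#'   kernel length scales >= 0.05 A^2 and bond widths >= 0.02 A; halve it to
#'   check convergence.
#' @param jitter_start,jitter_max Diagonal jitter for Cholesky
#'   factorizations, relative to the maximum diagonal; escalated by factors
#'   of 10 from `jitter_start` to `jitter_max` before failing.
#' @param maxit Maximum L-BFGS-B iterations per restart.
#' @param factr L-BFGS-B convergence factor (see [stats::optim()]).
#' @return A list of class `gp_control`.
#' @export
gp_control <- function(r_max = 25, r_step = 0.02,
                       jitter_start = 1e-10, jitter_max = 1e-4,
                       maxit = 100, factr = 1e8) {
  stopifnot(r_max > 0, r_step > 0, r_step < r_max)
  structure(list(r_max = r_max, r_step = r_step,
                 jitter_start = jitter_start, jitter_max = jitter_max,
                 maxit = maxit, factr = factr),
            class = "gp_control")
}

# Internal fitting geometry: uniform r grid from 0 and the inverse-direction
# quadrature matrix mapping r-space functions to the data's q points.
make_geometry <- function(q, density, control) {
  r <- seq(0, control$r_max, by = control$r_step)
  A <- if (length(q) > 0) {
    rft_operator(r, q, density, "inverse")$weights
  } else {
    matrix(0, 0, length(r))
  }
  list(r = r, A = A, density = density)
}

# Cholesky with escalating relative jitter; errors with a conditioning
# message once jitter_max is exceeded.
chol_jitter <- function(C, control = gp_control()) {
  scale <- max(diag(C))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 0
  repeat {
    L <- tryCatch(chol(C + diag(jit * scale, nrow(C))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) control$jitter_start else jit * 10
    if (jit > control$jitter_max) {
      stop("Cholesky factorization failed even with jitter ",
           control$jitter_max, " * max diagonal: covariance is too ",
           "ill-conditioned (check hyperparameters)", call. = FALSE)
    }
  }
}

# Core Gaussian log marginal likelihood given residuals and the noisy
# training covariance; symmetric factorization, no explicit inverse.
lml_core <- function(resid, C, control = gp_control()) {
  d <- length(resid)
  L <- chol_jitter(C, control)
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  -0.5 * sum(resid * alpha) - sum(log(diag(L))) - d / 2 * log(2 * pi)
}

# Training covariance C = K_qq + noise diagonal, residual, and pieces reused
# by posterior computations.
training_blocks <- function(data, hp, geom, control) {
  q <- data$q
  Mq <- gram_mult(t(geom$A), geom$r, hp$kernel)      # K_rr %*% t(A)  (n x d)
  Kqq <- geom$A %*% Mq
  Kqq <- (Kqq + t(Kqq)) / 2
  mu_q <- 1 + drop(geom$A %*% (mean_rdf(geom$r, hp$mean) - 1))
  noise_diag <- if ("sd" %in% names(data)) data$sd^2 else rep(hp$noise^2, nrow(data))
  list(Kqq = Kqq, C = Kqq + diag(noise_diag, nrow(data)),
       mu_q = mu_q, resid = data$S - mu_q, Mq = Mq)
}

#' Log marginal likelihood of a scattering dataset under the GP prior
#'
#' The Gaussian evidence
#' `-1/2 (Y - mu_q)' (K_qq + omega^2 I)^-1 (Y - mu_q) - 1/2 log det(K_qq + omega^2 I) - d/2 log 2 pi`,
#' computed through a Cholesky factorization with escalating jitter. The
#' prior mean and kernel are defined in r-space and mapped to the data's
#' q points by the discretized radial Fourier transform.
#'
#' @param data A [scattering_data()] with `d >= 2` rows.
#' @param hp An [rdf_hyperparams()] object.
#' @param control A [gp_control()] object.
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(data, hp, control = gp_control()) {
  stopifnot(inherits(data, "scattering_data"), inherits(hp, "rdf_hyperparams"))
  if (nrow(data) < 2L) stop("log_marginal_likelihood needs d >= 2", call. = FALSE)
  geom <- make_geometry(data$q, attr(data, "density"), control)
  tb <- training_blocks(data, hp, geom, control)
  lml_core(tb$resid, tb$C, control)
}

# Shared posterior machinery. space = "q" or "r"; include_noise adds
# omega^2 to the predictive diagonal (q-space only: the predictive
# distribution of new *observations* rather than of the latent structure
# factor).
posterior_core <- function(data, hp, query, space, include_noise, control,
                           noise_free = FALSE) {
  stopifnot(inherits(data, "scattering_data"), inherits(hp, "rdf_hyperparams"))
  geom <- make_geometry(data$q, attr(data, "density"), control)
  d <- nrow(data)
  if (space == "q") {
    check_momentum_grid(query)
    Aq <- rft_operator(geom$r, query, geom$density, "inverse")$weights
    mu_star <- 1 + drop(Aq %*% (mean_rdf(geom$r, hp$mean) - 1))
    Kxx <- Aq %*% gram_mult(t(Aq), geom$r, hp$kernel)
  } else {
    check_radial_grid(query)
    mu_star <- mean_rdf(query, hp$mean)
    Kxx <- kernel_gram(query, query, kp = hp$kernel)
  }
  Kxx <- (Kxx + t(Kxx)) / 2
  if (d == 0L) {
    mean_post <- mu_star
    cov_post <- Kxx
  } else {
    tb <- training_blocks(data, hp, geom, control)
    Kxq <- if (space == "q") Aq %*% tb$Mq
           else kernel_gram(query, geom$r, kp = hp$kernel) %*% t(geom$A)
    L <- chol_jitter(tb$C, control)
    alpha <- backsolve(L, forwardsolve(t(L), tb$resid))
    mean_post <- mu_star + drop(Kxq %*% alpha)
    V <- forwardsolve(t(L), t(Kxq))
    cov_post <- Kxx - crossprod(V)
    cov_post <- (cov_post + t(cov_post)) / 2
  }
  if (space == "q" && include_noise && hp$noise > 0) {
    cov_post <- cov_post + diag(hp$noise^2, length(query))
  }
  structure(list(space = space, grid = query, mean = mean_post,
                 cov = cov_post, noise_free = noise_free,
                 hyperparams = hp, density = geom$density),
            class = "rdf_posterior")
}

resolve_fit <- function(object, hp, control) {
  if (inherits(object, "rdf_gp")) {
    list(data = object$data,
         hp = hp %||% object$hyperparams,
         control = control %||% object$control)
  } else {
    if (is.null(hp)) stop("hp is required when the first argument is a dataset",
                          call. = FALSE)
    list(data = object, hp = hp, control = control %||% gp_control())
  }
}

#' Structure-factor posterior on a query q-grid
#'
#' Exact GP conditioning of the physics-informed prior on the observed
#' structure factor. All covariance blocks are obtained by transforming the
#' r-space prior kernel through the discretized radial Fourier transform.
#' With `include_noise = TRUE` (default) the returned covariance describes
#' new noisy observations (omega^2 added to the diagonal); with `FALSE` it
#' is the latent-function posterior of Eq.-style conditioning (see
#' [noise_free_posterior()]).
#'
#' With an empty dataset the prior itself is returned.
#'
#' @param object A [scattering_data()] (then `hp` is required) or a fitted
#'   [fit_rdf_gp()] object.
#' @param query Strictly increasing positive q values (1/angstrom).
#' @param hp An [rdf_hyperparams()] object (ignored for fits unless given).
#' @param include_noise Add omega^2 to the predictive diagonal.
#' @param control A [gp_control()].
#' @return An `rdf_posterior` object (grid, mean, cov, space tag).
#' @export
posterior_q <- function(object, query, hp = NULL, include_noise = TRUE,
                        control = NULL) {
  a <- resolve_fit(object, hp, control)
  posterior_core(a$data, a$hp, query, "q", include_noise, a$control)
}

#' RDF posterior on a query r-grid
#'
#' The latent g(r) posterior obtained by propagating the q-space
#' conditioning through the linearity of the radial Fourier transform:
#' `mean = mu_r + K_rq (K_qq + omega^2 I)^-1 (Y - mu_q)` and
#' `cov = K_rr - K_rq (K_qq + omega^2 I)^-1 K_qr`, with `mu_r` the prior
#' mean evaluated directly on the query grid.
#'
#' @param object A [scattering_data()] (then `hp` is required) or a fitted
#'   [fit_rdf_gp()] object.
#' @param query Strictly increasing nonnegative r values (angstrom).
#' @inheritParams posterior_q
#' @return An `rdf_posterior` object.
#' @export
posterior_r <- function(object, query, hp = NULL, control = NULL) {
  a <- resolve_fit(object, hp, control)
  posterior_core(a$data, a$hp, query, "r", include_noise = FALSE, a$control)
}

#' Noise-free (latent-function) posterior
#'
#' Identical conditioning to [posterior_q()]/[posterior_r()] except that the
#' observation noise omega^2 enters only the training-block inverse, never
#' the predictive variance: the posterior of the denoised latent structure
#' factor (or RDF). Used for visualizing error bars on the underlying
#' signal; its bands at training points lie strictly inside the noisy
#' predictive bands whenever omega > 0.
#'
#' @inheritParams posterior_q
#' @param space `"q"` or `"r"`.
#' @return An `rdf_posterior` with `noise_free = TRUE`.
#' @export
noise_free_posterior <- function(object, query, hp = NULL,
                                 space = c("q", "r"), control = NULL) {
  space <- match.arg(space)
  a <- resolve_fit(object, hp, control)
  posterior_core(a$data, a$hp, query, space, include_noise = FALSE,
                 a$control, noise_free = TRUE)
}

#' Draw samples from a posterior
#'
#' Multivariate-normal draws via a symmetric eigendecomposition of the
#' covariance (negative eigenvalues from roundoff are clamped to zero).
#' Identical seeds give identical samples.
#'
#' @param post An `rdf_posterior`.
#' @param n_samples Number of draws, `>= 1`.
#' @param seed Integer seed.
#' @return `n_samples` x `length(grid)` matrix of draws.
#' @export
sample_posterior <- function(post, n_samples, seed = 1L) {
  stopifnot(inherits(post, "rdf_posterior"), n_samples >= 1)
  m <- length(post$grid)
  ed <- eigen(post$cov, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  Lf <- ed$vectors %*% (sqrt(lam) * t(ed$vectors))
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n_samples * m), n_samples, m))
  sweep(Z %*% Lf, 2, post$mean, "+")
}

#' @export
print.rdf_posterior <- function(x, ...) {
  cat(sprintf("<rdf_posterior> %s-space, %d grid points%s\n",
              x$space, length(x$grid),
              if (isTRUE(x$noise_free)) ", noise-free" else ""))
  invisible(x)
}
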