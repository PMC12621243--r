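#' Pack hyperparameters into the flat named theta vector
#'
#' Order for simple liquids is `[r0, s0, l, max, slope, loc, decay, omega]`;
#' each bonded peak appends `(h_b, r_b, s_b)`. This is the vector the
#' optimizer works on (in log space).
#'
#' @param hp An [rdf_hyperparams()] object.
#' @return Named numeric vector.
#' @export
as_theta <- function(hp) {
  stopifnot(inherits(hp, "rdf_hyperparams"))
  v <- c(r0 = hp$mean$r0, s0 = hp$mean$s0,
         l = hp$kernel$l, max = hp$kernel$max, slope = hp$kernel$slope,
         loc = hp$kernel$loc, decay = hp$kernel$decay,
         omega = hp$noise)
  B <- nrow(hp$mean$bonded)
  if (B > 0) {
    for (b in seq_len(B)) {
      x <- c(hp$mean$bonded$h[b], hp$mean$bonded$r[b], hp$mean$bonded$s[b])
      names(x) <- paste0(c("h_b", "r_b", "s_b"), b)
      v <- c(v, x)
    }
  }
  v
}

theta_to_hp <- function(theta) {
  B <- (length(theta) - 8L) / 3L
  stopifnot(B == round(B), B >= 0)
  bonded <- NULL
  if (B > 0) {
    idx <- 8L + seq_len(3 * B)
    m <- matrix(theta[idx], ncol = 3, byrow = TRUE)
    bonded <- tibble::tibble(h = m[, 1], r = m[, 2], s = m[, 3])
  }
  rdf_hyperparams(
    mean = mean_params(r0 = theta[[1]], s0 = theta[[2]], bonded = bonded),
    kernel = kernel_params(l = theta[[3]], max = theta[[4]],
                           slope = theta[[5]], loc = theta[[6]],
                           decay = theta[[7]]),
    noise = theta[[8]]
  )
}

#' Default hyperparameter box bounds
#'
#' Physically plausible ranges for simple and molecular liquids, used as the
#' optimization box (in log space): excluded-volume onset 1-4 A, onset
#' sharpness 1-50 1/A, squared length scale 0.005-2 A^2, width amplitude
#' 0.1-500, sigmoid slope 0.5-20 1/A, center 1-6 A, decay 0.05-2 1/A, noise
#' sd 1e-4 to 1; bonded peaks: center 0.5-3 A, sd 0.01-0.3 A, amplitude
#' 0.01-10.
#'
#' @param n_bonded Number of bonded peaks in the mean.
#' @return Tibble with columns `param`, `lower`, `upper`.
#' @export
default_bounds <- function(n_bonded = 0) {
  base <- tibble::tribble(
    ~param,   ~lower, ~upper,
    "r0",     1,      4,
    "s0",     1,      50,
    "l",      0.005,  2,
    "max",    0.1,    500,
    "slope",  0.5,    20,
    "loc",    1,      6,
    "decay",  0.05,   2,
    "omega",  1e-4,   1
  )
  if (n_bonded > 0) {
    for (b in seq_len(n_bonded)) {
      base <- dplyr::bind_rows(base, tibble::tribble(
        ~param,               ~lower, ~upper,
        paste0("h_b", b),     0.01,   10,
        paste0("r_b", b),     0.5,    3,
        paste0("s_b", b),     0.01,   0.3
      ))
    }
  }
  base
}

#' Fit the nonstationary GP by type-II maximum likelihood
#'
#' Maximizes the log marginal likelihood over the full hyperparameter vector
#' with bounded quasi-Newton (L-BFGS-B) in log-parameter space, using
#' `n_restarts` seeded starting points drawn uniformly in the log box (the
#' supplied `init` is always the first start). Restarts whose factorization
#' fails are dropped; the best surviving restart is returned. When the data
#' carry a per-point `sd` column that fixed diagonal replaces omega^2 I and
#' omega is frozen at its initial value.
#'
#' @param data A [scattering_data()] with `d >= 2`.
#' @param init Initial [rdf_hyperparams()]. Its bonded-peak count fixes the
#'   number of bonded peaks of the model.
#' @param bounds Box bounds as from [default_bounds()]; defaults to them.
#'   Rows with `lower == upper` freeze that parameter.
#' @param n_restarts Number of optimization starts (first = `init`).
#' @param seed Integer seed controlling restart draws (deterministic).
#' @param control A [gp_control()]; `maxit`/`factr` bound each restart.
#' @return An object of class `rdf_gp`: optimized hyperparameters, final
#'   LML, the trace of accepted improvements, data, control, seed.
#' @export
fit_rdf_gp <- function(data, init, bounds = NULL, n_restarts = 10,
                       seed = 1L, control = gp_control()) {
  stopifnot(inherits(data, "scattering_data"), inherits(init, "rdf_hyperparams"))
  if (nrow(data) < 2L) stop("fit_rdf_gp needs d >= 2 observations", call. = FALSE)
  B <- nrow(init$mean$bonded)
  if (is.null(bounds)) bounds <- default_bounds(B)
  theta0 <- as_theta(init)
  if (!identical(bounds$param, names(theta0))) {
    stop("bounds rows must match the hyperparameter vector: ",
         paste(names(theta0), collapse = ", "), call. = FALSE)
  }
  hetero <- "sd" %in% names(data)
  free <- bounds$lower < bounds$upper
  if (hetero) free[bounds$param == "omega"] <- FALSE
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)

  geom <- make_geometry(data$q, attr(data, "density"), control)
  noise_diag <- if (hetero) data$sd^2 else NULL
  trace_env <- new.env()
  trace_env$rows <- list()
  trace_env$best <- -Inf
  trace_env$evals <- 0L
  cur_restart <- 0L

  lml_of_theta <- function(theta) {
    hp <- theta_to_hp(theta)
    Mq <- gram_mult(t(geom$A), geom$r, hp$kernel)
    Kqq <- geom$A %*% Mq
    Kqq <- (Kqq + t(Kqq)) / 2
    mu_q <- 1 + drop(geom$A %*% (mean_rdf(geom$r, hp$mean) - 1))
    nd <- if (hetero) noise_diag else rep(hp$noise^2, nrow(data))
    lml_core(data$S - mu_q, Kqq + diag(nd, nrow(data)), control)
  }
  objective <- function(lpar) {
    theta <- theta0
    theta[free] <- exp(lpar)
    val <- tryCatch(lml_of_theta(theta), error = function(e) -Inf)
    trace_env$evals <- trace_env$evals + 1L
    if (!is.finite(val)) return(1e10)
    if (val > trace_env$best) {
      trace_env$best <- val
      trace_env$theta <- theta
      trace_env$rows[[length(trace_env$rows) + 1L]] <-
        tibble::tibble(restart = cur_restart, eval = trace_env$evals, lml = val)
    }
    -val
  }
  # memoized forward-difference gradient: optim calls gr at the point it
  # just evaluated, so the base value is reused (9 instead of 17 LML
  # evaluations per L-BFGS-B iteration for a simple liquid)
  last <- new.env()
  obj_memo <- function(lpar) {
    v <- objective(lpar)
    last$x <- lpar; last$v <- v
    v
  }
  grad <- function(lpar) {
    v0 <- if (!is.null(last$x) && identical(last$x, lpar)) last$v
          else obj_memo(lpar)
    hstep <- 1e-4
    vapply(seq_along(lpar), function(i) {
      xp <- lpar; xp[i] <- xp[i] + hstep
      (objective(xp) - v0) / hstep
    }, numeric(1))
  }

  starts <- list(log(theta0[free]))
  if (n_restarts > 1) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts - 1), function(i) {
        for (try in 1:200) {
          lp <- stats::runif(sum(free), lo[free], hi[free])
          th <- theta0; th[free] <- exp(lp)
          ok <- tryCatch({ theta_to_hp(th); TRUE }, error = function(e) FALSE)
          if (ok) return(lp)
        }
        stop("could not draw a valid restart inside the bounds", call. = FALSE)
      })
    })
    starts <- c(starts, extra)
  }

  results <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    cur_restart <- i
    results[[i]] <- tryCatch(
      stats::optim(starts[[i]], obj_memo, gr = grad, method = "L-BFGS-B",
                   lower = lo[free], upper = hi[free],
                   control = list(maxit = control$maxit,
                                  factr = control$factr)),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, logical(1))
  vals <- vapply(results, function(r) if (is.null(r)) Inf else r$value,
                 numeric(1))
  if (!any(ok & is.finite(vals) & vals < 1e9)) {
    stop("all optimization restarts failed to factorize; the model is ",
         "ill-conditioned for this dataset", call. = FALSE)
  }
  best_i <- which.min(vals)
  best <- results[[best_i]]
  # the best point ever evaluated can beat the optimizer's returned point
  # (gradient probes are real evaluations); keep whichever is highest, and
  # never return something worse than the init (monotone acceptance)
  theta_hat <- theta0
  theta_hat[free] <- exp(best$par)
  lml_hat <- -best$value
  if (trace_env$best > lml_hat) {
    theta_hat <- trace_env$theta
    lml_hat <- trace_env$best
  }
  hp_hat <- theta_to_hp(theta_hat)
  lml_init <- tryCatch(lml_of_theta(theta0), error = function(e) -Inf)
  if (is.finite(lml_init) && lml_init > lml_hat) {
    hp_hat <- theta_to_hp(theta0)
    lml_hat <- lml_init
    best_i <- 0L
  }
  structure(list(
    hyperparams = hp_hat, lml = lml_hat, lml_init = lml_init,
    trace = dplyr::bind_rows(trace_env$rows),
    data = data, control = control, bounds = bounds, seed = seed,
    init = init, n_restarts = n_restarts, best_restart = best_i,
    convergence = best$convergence, n_evals = trace_env$evals,
    heteroscedastic = hetero), class = "rdf_gp")
}

#' @export
print.rdf_gp <- function(x, ...) {
  cat(sprintf(
    "<rdf_gp> d = %d observations, log marginal likelihood = %.4f\n",
    nrow(x$data), x$lml))
  cat("hyperparameters:\n")
  print(round(as_theta(x$hyperparams), 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the optimized hyperparameters of a GP fit
#'
#' @param x An `rdf_gp` fit.
#' @param ... Unused.
#' @return Tibble with columns `param`, `estimate`, `lower`, `upper`, `unit`.
#' @method tidy rdf_gp
#' @export
tidy.rdf_gp <- function(x, ...) {
  th <- as_theta(x$hyperparams)
  units <- c(r0 = "A", s0 = "1/A", l = "A^2", max = "", slope = "1/A",
             loc = "A", decay = "1/A", omega = "")
  u <- units[names(th)]
  u[is.na(u)] <- ifelse(grepl("^h_b", names(th)[is.na(u)]), "",
                        ifelse(grepl("^r_b", names(th)[is.na(u)]), "A", "A"))
  tibble::tibble(param = names(th), estimate = unname(th),
                 lower = x$bounds$lower, upper = x$bounds$upper,
                 unit = unname(u))
}

#' One-row summary of a GP fit
#'
#' @param x An `rdf_gp` fit.
#' @param ... Unused.
#' @return Tibble with the final LML, data size, restart bookkeeping.
#' @method glance rdf_gp
#' @export
glance.rdf_gp <- function(x, ...) {
  tibble::tibble(logLik = x$lml, lml_init = x$lml_init, d = nrow(x$data),
                 n_restarts = x$n_restarts, best_restart = x$best_restart,
                 n_evals = x$n_evals, convergence = x$convergence,
                 heteroscedastic = x$heteroscedastic)
}

#' Tidy a posterior into a band table
#'
#' @param x An `rdf_posterior`.
#' @param level Credible-band level (default 0.95).
#' @param ... Unused.
#' @return Tibble with the grid column (`r` or `q`), `mean`, `sd`, `lower`,
#'   `upper`.
#' @method tidy rdf_posterior
#' @export
tidy.rdf_posterior <- function(x, level = 0.95, ...) {
  sd <- sqrt(pmax(diag(x$cov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(grid = x$grid, mean = x$mean, sd = sd,
                        lower = x$mean - z * sd, upper = x$mean + z * sd)
  names(out)[1] <- x$space
  out
}
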