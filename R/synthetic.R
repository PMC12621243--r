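# Synthetic ground-truth RDFs and corrupted structure-factor measurements.
# The damped-cosine family stands in for simulation output: it reproduces
# the statistical structure of real liquids (excluded volume, decaying
# solvation oscillations, bonded peaks) without being literal argon/water
# truth.

synthetic_defaults <- function(system) {
  switch(system,
    # argon-like: printed argon density; first shell near 3.7 A
    "argon" = list(density = 0.02125, r0 = 3.0, s0 = 8, r_p = 3.7,
                   amplitude = 1.2, xi = 2.5, lambda = 3.4, bonded = NULL),
    # water-like partials at 1 g/cm^3 (0.03343 molecules/A^3); rho is the
    # number density of the shell species of the pair
    "water-OO" = list(density = 0.03343, r0 = 2.4, s0 = 10, r_p = 2.8,
                      amplitude = 1.6, xi = 1.6, lambda = 2.9, bonded = NULL),
    "water-OH" = list(density = 0.06686, r0 = 1.5, s0 = 10, r_p = 1.85,
                      amplitude = 0.9, xi = 1.8, lambda = 2.9,
                      bonded = tibble::tibble(h = 1.0, r = 0.96, s = 0.05)),
    "water-HH" = list(density = 0.06686, r0 = 1.9, s0 = 9, r_p = 2.4,
                      amplitude = 0.7, xi = 2.0, lambda = 2.9,
                      bonded = tibble::tibble(h = 1.0, r = 1.6, s = 0.08)),
    stop("unknown synthetic system: ", system, call. = FALSE)
  )
}

#' Generate a ground-truth model RDF
#'
#' Builds a synthetic g(r) of the form
#' `sigmoid excluded volume x (1 + A exp(-(r - r_p)/xi) cos(2 pi (r - r_p)/lambda))`
#' for `r > r_p` (constant `1 + A` below the first-shell radius `r_p`, so
#' the oscillation starts at its crest), plus optional bonded Gaussian
#' terms; continuous, clipped at 0, and satisfying both RDF limits
#' (g -> 0 at r -> 0, g -> 1 at large r).
#'
#' Available systems: `"argon"` (no bonds, rho = 0.02125 atoms/A^3, the
#' printed argon density), and the water-like partials `"water-OO"`,
#' `"water-OH"` (O-H bond peak at 0.96 A), `"water-HH"` (intramolecular
#' H-H peak near 1.6 A) at 1 g/cm^3.
#'
#' @param system One of `"argon"`, `"water-OO"`, `"water-OH"`, `"water-HH"`.
#' @param r Radial grid (angstrom); default `seq(0, 25, 0.005)`.
#' @param params Optional named list overriding the system defaults
#'   (`density`, `r0`, `s0`, `r_p`, `amplitude`, `xi`, `lambda`, `bonded`).
#' @return An object of class `synthetic_system`: tibble `(r, g)` with the
#'   system label, density and generator parameters attached.
#' @export
synthetic_rdf <- function(system = c("argon", "water-OO", "water-OH", "water-HH"),
                          r = seq(0, 25, by = 0.005), params = list()) {
  system <- match.arg(system)
  check_radial_grid(r)
  p <- utils::modifyList(synthetic_defaults(system), params)
  stopifnot(p$density > 0, p$r0 > 0, p$s0 > 0, p$r_p > p$r0,
            p$amplitude > 0, p$xi > 0, p$lambda > 0)
  x <- pmax(r - p$r_p, 0)
  osc <- 1 + p$amplitude * exp(-x / p$xi) * cos(2 * pi * x / p$lambda)
  sig <- 1 / (1 + safe_exp(-p$s0 * (r - p$r0)))
  g <- pmax(sig * osc, 0)
  if (!is.null(p$bonded) && nrow(p$bonded) > 0) {
    for (b in seq_len(nrow(p$bonded))) {
      g <- g + p$bonded$h[b] * stats::dnorm(r, p$bonded$r[b], p$bonded$s[b])
    }
  }
  structure(tibble::tibble(r = r, g = g),
            system = system, density = p$density, params = p,
            class = c("synthetic_system", "tbl_df", "tbl", "data.frame"))
}

#' Transform a ground-truth RDF to its structure factor
#'
#' `S(q) = 1 + H^-1[g(r) - 1]` through the inverse-direction discretized
#' radial Fourier transform on the system's dense r grid.
#'
#' @param system A [synthetic_rdf()] object (or any tibble with `r`, `g`
#'   plus a `density` attribute).
#' @param q Momentum-transfer grid (1/angstrom); default
#'   `seq(1e-4, 30, by = 0.005)`.
#' @return Tibble `(q, S)`, with the density attached.
#' @export
rdf_to_sq <- function(system, q = seq(1e-4, 30, by = 0.005)) {
  stopifnot(all(c("r", "g") %in% names(system)))
  rho <- attr(system, "density")
  if (is.null(rho)) stop("rdf_to_sq: system must carry a density attribute",
                         call. = FALSE)
  op <- rft_operator(system$r, q, rho, "inverse")
  out <- tibble::tibble(q = q, S = 1 + apply_rft(op, system$g - 1))
  attr(out, "density") <- rho
  out
}

#' Corrupt an ideal structure factor into a measurement
#'
#' Emulates a detector: resamples the dense S(q) curve onto a binned grid
#' `seq(q_min, q_max, by = delta_q)` (bin-center value by linear
#' interpolation), crops to the finite window, and adds i.i.d. Gaussian
#' noise of variance `noise_var` (homoscedastic, the reactor-source
#' assumption). Seeded and deterministic.
#'
#' @param sq Tibble `(q, S)` on a dense grid (from [rdf_to_sq()]), carrying
#'   a `density` attribute, or pass `density` explicitly.
#' @param delta_q Detector bin width (1/angstrom), `>=` the dense grid step.
#' @param q_min,q_max Measurement window (1/angstrom).
#' @param noise_var Gaussian noise variance (dimensionless); the argon
#'   benchmark value is 0.04.
#' @param seed Integer seed.
#' @param density Atomic number density; defaults to the attribute on `sq`.
#' @return A [scattering_data()] object.
#' @export
corrupt_measurement <- function(sq, delta_q, q_min, q_max, noise_var,
                                seed = 1L, density = attr(sq, "density")) {
  stopifnot(all(c("q", "S") %in% names(sq)), noise_var >= 0)
  if (q_min >= q_max) stop("q_min must be below q_max", call. = FALSE)
  if (q_min < min(sq$q) - 1e-9 || q_max > max(sq$q) + 1e-9) {
    stop("window [q_min, q_max] must lie inside the dense grid", call. = FALSE)
  }
  step <- min(diff(sq$q))
  if (delta_q < step - 1e-12) {
    stop("delta_q must be at least the dense grid step", call. = FALSE)
  }
  qb <- seq(q_min, q_max, by = delta_q)
  Sb <- stats::approx(sq$q, sq$S, xout = qb)$y
  noise <- if (noise_var > 0) {
    withr::with_seed(seed, stats::rnorm(length(qb), 0, sqrt(noise_var)))
  } else rep(0, length(qb))
  scattering_data(tibble::tibble(q = qb, S = Sb + noise), density = density)
}

#' Faber-Ziman composition of partial structure factors
#'
#' Total structure factor `F(q) = sum_{i >= j} (2 - delta_ij) w_ij S_ij(q)`
#' with constant (neutron-like) weights; like pairs enter once, unlike pairs
#' twice.
#'
#' @param partials Named list of numeric S_ij vectors on a common q-grid.
#' @param weights Data frame with columns `pair` (matching the names of
#'   `partials`), `like` (logical: i == j), `w` (finite weights).
#' @return Numeric vector F(q).
#' @export
faber_ziman_total <- function(partials, weights) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("pair", "like", "w") %in% names(weights)),
            all(is.finite(weights$w)))
  if (anyDuplicated(weights$pair)) {
    stop("each pair may appear only once", call. = FALSE)
  }
  if (!setequal(names(partials), weights$pair)) {
    stop("weights$pair must match names(partials)", call. = FALSE)
  }
  len <- unique(vapply(partials, length, integer(1)))
  if (length(len) != 1L) stop("all partials must share one q-grid", call. = FALSE)
  out <- numeric(len)
  for (k in seq_len(nrow(weights))) {
    fac <- if (weights$like[k]) 1 else 2
    out <- out + fac * weights$w[k] * partials[[weights$pair[k]]]
  }
  out
}
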