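#' Nonstationary Gibbs kernel parameters
#'
#' Parameters of the symmetrized Gibbs kernel with a constant squared length
#' scale `l` and a decaying-sigmoid width function. `max` sets the overall
#' width amplitude, `loc` and `slope` the position and sharpness of the
#' sigmoid rise, and `decay` the large-r exponential decay rate that drives
#' the prior variance to zero where g(r) must approach 1.
#'
#' `slope > decay` is required: the width evaluated at -r (needed by the
#' r = 0 symmetrization) behaves as `exp((decay - slope) r)` for large r, so
#' the symmetrized kernel is bounded only under net decay.
#'
#' @param l Squared length scale (angstrom^2), positive.
#' @param max Width amplitude (dimensionless), positive.
#' @param slope Sigmoid sharpness (1/angstrom), positive.
#' @param loc Sigmoid center (angstrom), positive.
#' @param decay Exponential decay rate (1/angstrom), positive, `< slope`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(l, max, slope, loc, decay) {
  vals <- c(l = l, max = max, slope = slope, loc = loc, decay = decay)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kernel_params: all of l, max, slope, loc, decay must be finite and > 0",
         call. = FALSE)
  }
  if (slope <= decay) {
    stop("kernel_params: slope must exceed decay (the symmetrized kernel's ",
         "negative-r branch grows without bound otherwise)", call. = FALSE)
  }
  structure(as.list(vals), class = "kernel_params")
}

#' GP mean-function parameters
#'
#' The prior mean for g(r): a sigmoid excluded-volume onset (`r0`, `s0`)
#' rising from 0 to 1, plus an optional sum of Gaussian bonded peaks, one row
#' per intramolecular feature (e.g. the O-H bond, or the intramolecular H-H
#' distance in water near 1.6 angstrom).
#'
#' @param r0 Excluded-volume onset (angstrom), positive.
#' @param s0 Onset sharpness (1/angstrom), positive.
#' @param bonded Data frame with columns `h` (amplitude), `r` (peak center,
#'   angstrom), `s` (peak sd, angstrom), all positive; or `NULL` for no
#'   bonded contribution (simple liquids such as argon).
#' @return An object of class `mean_params`.
#' @export
mean_params <- function(r0, s0, bonded = NULL) {
  if (!is.numeric(r0) || !is.numeric(s0) || anyNA(c(r0, s0)) ||
      r0 <= 0 || s0 <= 0) {
    stop("mean_params: r0 and s0 must be positive", call. = FALSE)
  }
  if (is.null(bonded)) {
    bonded <- tibble::tibble(h = numeric(), r = numeric(), s = numeric())
  } else {
    bonded <- tibble::as_tibble(bonded)
    if (!all(c("h", "r", "s") %in% names(bonded))) {
      stop("mean_params: bonded needs columns h, r, s", call. = FALSE)
    }
    bonded <- bonded[c("h", "r", "s")]
    if (nrow(bonded) > 0 &&
        (anyNA(bonded) || any(as.matrix(bonded) <= 0))) {
      stop("mean_params: bonded peak parameters must all be positive",
           call. = FALSE)
    }
  }
  structure(list(r0 = r0, s0 = s0, bonded = bonded), class = "mean_params")
}

# exp with exponent clamped at +/-700 to avoid overflow; underflow -> 0.
safe_exp <- function(x) exp(pmin(pmax(x, -700), 700))

#' Width function of the nonstationary kernel
#'
#' `sigma(r) = max * exp(decay*loc) / (1 + exp(-slope*(r - loc))) * exp(-r*decay)`,
#' evaluated in a numerically safe form (single combined exponent per branch,
#' clamped before exponentiation; no overflow for |r| <= 100). Negative r is
#' allowed: the r = 0 symmetrization of the kernel evaluates sigma(-r).
#'
#' At r = loc the sigmoid is 1/2 and the exponential factors cancel, giving
#' sigma(loc) = max/2.
#'
#' @param r Distance (angstrom); may be negative.
#' @param kp A [kernel_params()] object.
#' @return Width values (dimensionless), same length as `r`.
#' @export
width_sigma <- function(r, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  # sigma(r) = max * exp(decay*(loc - r)) / (1 + exp(-slope*(r - loc)))
  # Two algebraically equal branches, each with bounded exponents:
  #   r >= loc: max * exp(decay*(loc-r)) / (1 + exp(-slope*(r-loc)))
  #   r <  loc: max * exp(decay*(loc-r) + slope*(r-loc)) / (1 + exp(slope*(r-loc)))
  u <- kp$slope * (r - kp$loc)
  e <- kp$decay * (kp$loc - r)
  ifelse(u >= 0,
         kp$max * safe_exp(e) / (1 + safe_exp(-u)),
         kp$max * safe_exp(e + u) / (1 + safe_exp(u)))
}

#' Gibbs kernel with constant length scale
#'
#' `K(r, r') = sigma(r) sigma(r') sqrt(2 l l / (l + l)) exp(-(r - r')^2 / (l + l))`,
#' which with constant `l` reduces to
#' `sigma(r) sigma(r') sqrt(l) exp(-(r - r')^2 / (2 l))`. Note the printed
#' normalization carries a factor `sqrt(l)` on the diagonal:
#' `K(r, r) = sigma(r)^2 sqrt(l)`.
#'
#' @param r,rp Distances (angstrom); vectorized with recycling. May be
#'   negative (used by the symmetrization).
#' @param kp A [kernel_params()] object.
#' @return Covariance values.
#' @export
gibbs_kernel <- function(r, rp, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  width_sigma(r, kp) * width_sigma(rp, kp) * sqrt(kp$l) *
    safe_exp(-(r - rp)^2 / (2 * kp$l))
}

#' Symmetrized Gibbs kernel
#'
#' `K_sym(r, r') = K(r, r') + K(-r, r')`, making the process even about
#' r = 0 so the GP behaves consistently on the full real line even though
#' g(r) lives on r >= 0. Requires `slope > decay` (enforced by
#' [kernel_params()]) so the negative branch decays.
#'
#' The two-term sum is exactly even in each argument; it is symmetric under
#' argument exchange only up to a term of order `exp(-(slope - decay) r)`,
#' so Gram-matrix builders symmetrize by transpose-averaging.
#'
#' @inheritParams gibbs_kernel
#' @return Covariance values.
#' @export
gibbs_kernel_sym <- function(r, rp, kp) {
  gibbs_kernel(r, rp, kp) + gibbs_kernel(-r, rp, kp)
}

#' Gram matrix of the symmetrized kernel on or between grids
#'
#' Builds the Gram matrix of the symmetrized Gibbs kernel in its
#' exchange-symmetrized form
#' `sqrt(l) * (sigma(r) sigma(r') E- + (sigma(-r) sigma(r') + sigma(r) sigma(-r')) / 2 * E+)`
#' with `E- = exp(-(r - r')^2 / 2l)` and `E+ = exp(-(r + r')^2 / 2l)`.
#' This equals the transpose average of [gibbs_kernel_sym()] and is exactly
#' symmetric under argument exchange; the correction to the verbatim two-term
#' form is of order `exp(-(slope - decay) r)` and is what every covariance
#' computation in the package uses.
#'
#' @param r,rp Grids (angstrom). `rp` defaults to `r`.
#' @param kp A [kernel_params()] object.
#' @return A `length(r)` x `length(rp)` matrix.
#' @export
kernel_gram <- function(r, rp = r, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  sr <- width_sigma(r, kp)
  smr <- width_sigma(-r, kp)
  sp <- width_sigma(rp, kp)
  smp <- width_sigma(-rp, kp)
  dm <- outer(r, rp, "-")
  ds <- outer(r, rp, "+")
  sqrt(kp$l) * (outer(sr, sp) * safe_exp(-dm^2 / (2 * kp$l)) +
                0.5 * (outer(smr, sp) + outer(sr, smp)) *
                  safe_exp(-ds^2 / (2 * kp$l)))
}

#' Nonbonded (excluded-volume) part of the prior mean
#'
#' The sigmoid `1 / (1 + exp(-s0 (r - r0)))`, 0 inside the excluded volume
#' and 1 at large r, preserving the fluid's bulk density.
#'
#' @param r Distances (angstrom).
#' @param mp A [mean_params()] object.
#' @return Mean values (dimensionless).
#' @export
mean_nonbonded <- function(r, mp) {
  stopifnot(inherits(mp, "mean_params"))
  x <- mp$s0 * (r - mp$r0)
  ifelse(x >= 0, 1 / (1 + safe_exp(-x)), safe_exp(x) / (1 + safe_exp(x)))
}

#' Bonded part of the prior mean
#'
#' Sum over intramolecular peaks of `h_b * N(r | r_b, s_b)` with N the
#' normal density; 0 when no peaks are declared.
#'
#' @inheritParams mean_nonbonded
#' @return Mean values (dimensionless).
#' @export
mean_bonded <- function(r, mp) {
  stopifnot(inherits(mp, "mean_params"))
  if (nrow(mp$bonded) == 0L) return(numeric(length(r)) )
  out <- numeric(length(r))
  for (b in seq_len(nrow(mp$bonded))) {
    out <- out + mp$bonded$h[b] *
      stats::dnorm(r, mean = mp$bonded$r[b], sd = mp$bonded$s[b])
  }
  out
}

#' Full prior mean for g(r)
#'
#' `mean_bonded + mean_nonbonded`; approximately 0 as r -> 0 (within the
#' sigmoid tail) and exactly -> 1 as r -> infinity.
#'
#' @inheritParams mean_nonbonded
#' @return Mean values (dimensionless).
#' @export
mean_rdf <- function(r, mp) {
  mean_bonded(r, mp) + mean_nonbonded(r, mp)
}

#' Prior mean mapped to momentum space
#'
#' `mu_S(q) = 1 + H^-1[mu(r) - 1]` through an inverse-direction
#' [rft_operator()]; `mu(r) - 1` decays exponentially, so the truncated
#' quadrature converges on the operator's default grids.
#'
#' @param mp A [mean_params()] object.
#' @param op An inverse-direction [rft_operator()] (r -> q).
#' @return Numeric vector `mu_S` on the operator's target q-grid.
#' @export
mean_structure_factor <- function(mp, op) {
  stopifnot(inherits(op, "rft_operator"))
  if (op$direction != "inverse") {
    stop("mean_structure_factor needs an inverse-direction (r -> q) operator",
         call. = FALSE)
  }
  1 + apply_rft(op, mean_rdf(op$source, mp) - 1)
}
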