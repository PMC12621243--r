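#' Validate a radial (r-space) grid
#'
#' A radial grid is a strictly increasing vector of nonnegative distances in
#' angstroms. Used as the index set for g(r) and for quadrature in the radial
#' Fourier transform.
#'
#' @param r Numeric vector of distances (angstrom).
#' @return The input, invisibly, after validation.
#' @keywords internal
check_radial_grid <- function(r) {
  if (!is.numeric(r) || length(r) < 1L || anyNA(r) || any(!is.finite(r))) {
    stop("radial grid must be a finite numeric vector", call. = FALSE)
  }
  if (r[1] < 0) stop("radial grid values must be nonnegative", call. = FALSE)
  if (length(r) > 1L && any(diff(r) <= 0)) {
    stop("radial grid must be strictly increasing", call. = FALSE)
  }
  invisible(r)
}

#' Validate a momentum-transfer (q-space) grid
#'
#' Strictly increasing, strictly positive momentum transfers in inverse
#' angstroms. q = 0 is excluded (the integrand is defined there only as a
#' limit; callers wanting the q -> 0 value use an arbitrarily small q).
#'
#' @param q Numeric vector of momentum transfers (1/angstrom).
#' @return The input, invisibly, after validation.
#' @keywords internal
check_momentum_grid <- function(q) {
  if (!is.numeric(q) || length(q) < 1L || anyNA(q) || any(!is.finite(q))) {
    stop("momentum grid must be a finite numeric vector", call. = FALSE)
  }
  if (q[1] <= 0) stop("momentum grid values must be strictly positive", call. = FALSE)
  if (length(q) > 1L && any(diff(q) <= 0)) {
    stop("momentum grid must be strictly increasing", call. = FALSE)
  }
  invisible(q)
}

# Trapezoid quadrature weights for an arbitrary strictly increasing grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 grid points for quadrature", call. = FALSE)
  h <- diff(x)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}
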