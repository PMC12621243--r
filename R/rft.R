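#' Spherical sinc kernel sin(qr)/(qr)
#'
#' The kernel of the radial Fourier transform relating the structure factor
#' S(q) and the radial distribution function g(r) under spherical symmetry.
#' The removable singularity at qr = 0 is filled with its limit value 1;
#' below a small-argument threshold the Taylor series
#' `1 - x^2/6 + x^4/120` is used (at the default threshold the quadratic
#' term is already below double-precision resolution).
#'
#' @param q Momentum transfer (1/angstrom), nonnegative. Recycled against `r`.
#' @param r Distance (angstrom), nonnegative. Recycled against `q`.
#' @param threshold Small-argument cutoff on |qr| below which the series
#'   evaluation is used. Default `1e-8`.
#' @return Numeric vector of kernel values (dimensionless).
#' @examples
#' sinc_qr(0, 2.5)      # limit value 1
#' sinc_qr(pi, 1)       # sin(pi)/pi = 0 (to machine precision)
#' @export
sinc_qr <- function(q, r, threshold = 1e-8) {
  if (any(q < 0, na.rm = TRUE) || any(r < 0, na.rm = TRUE)) {
    stop("sinc_qr: q and r must be nonnegative", call. = FALSE)
  }
  x <- q * r
  out <- ifelse(abs(x) < threshold,
                1 - x^2 / 6 + x^4 / 120,
                sin(x) / x)
  out
}

#' Build a discretized radial Fourier transform operator
#'
#' Constructs the dense linear map implementing trapezoid quadrature of
#' `prefactor * integral f(x) sinc(q r) x^2 dx` over the source grid, one
#' output row per target point. The forward direction maps deviations
#' S(q) - 1 on a q-grid to g(r) - 1 on an r-grid with prefactor
#' `1/(2 pi^2 rho)`; the inverse maps g(r) - 1 to S(q) - 1 with prefactor
#' `4 pi rho`. The operator acts on baseline-subtracted values; callers add
#' the ideal-gas 1 back.
#'
#' @param source Source grid: a strictly increasing numeric vector
#'   (q in 1/angstrom for `direction = "forward"`, r in angstrom for
#'   `"inverse"`).
#' @param target Target grid (the Fourier-dual variable).
#' @param density Atomic number density rho (atoms/angstrom^3), positive.
#' @param direction `"forward"` (q -> r) or `"inverse"` (r -> q).
#' @return An object of class `rft_operator` with fields `weights`
#'   (|target| x |source| matrix), `source`, `target`, `density`,
#'   `direction`.
#' @seealso [apply_rft()], [transform_kernel()]
#' @export
rft_operator <- function(source, target, density,
                         direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a single positive number (atoms/angstrom^3)",
         call. = FALSE)
  }
  if (length(source) < 2L) {
    stop("source grid needs at least 2 points for quadrature", call. = FALSE)
  }
  if (direction == "forward") {
    check_momentum_grid(source)
    check_radial_grid(target)
    prefactor <- 1 / (2 * pi^2 * density)
  } else {
    check_radial_grid(source)
    check_momentum_grid(target)
    prefactor <- 4 * pi * density
  }
  w <- trapezoid_weights(source)
  # weights[t, s] = prefactor * w_s * source_s^2 * sinc(target_t * source_s)
  x <- outer(target, source)                    # t(q r) arguments
  K <- ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  W <- prefactor * K * matrix(w * source^2, nrow = length(target),
                              ncol = length(source), byrow = TRUE)
  structure(
    list(weights = W, source = source, target = target,
         density = density, direction = direction),
    class = "rft_operator"
  )
}

#' @export
print.rft_operator <- function(x, ...) {
  cat(sprintf(
    "<rft_operator> %s: %d source points -> %d target points, rho = %g\n",
    x$direction, length(x$source), length(x$target), x$density))
  invisible(x)
}

#' Apply a radial Fourier transform operator to function values
#'
#' Matrix-vector product of the discretized operator with baseline-subtracted
#' function values on the source grid (S - 1 for the inverse direction,
#' g - 1 for the forward direction is *produced*, not consumed: the forward
#' operator consumes S - 1 and produces g - 1).
#'
#' @param op An [rft_operator()].
#' @param values Numeric vector on the source grid (baseline already
#'   subtracted), or a matrix with one column per function.
#' @return Numeric vector (or matrix) on the target grid.
#' @export
apply_rft <- function(op, values) {
  stopifnot(inherits(op, "rft_operator"))
  v <- as.matrix(values)
  if (nrow(v) != length(op$source)) {
    stop(sprintf("apply_rft: expected %d source values, got %d",
                 length(op$source), nrow(v)), call. = FALSE)
  }
  out <- op$weights %*% v
  if (is.matrix(values)) out else drop(out)
}

#' Transform a kernel matrix between Fourier-dual spaces
#'
#' Propagates a covariance (kernel Gram) matrix through the linear transform:
#' applying the operator along the rows gives the cross-covariance
#' K(target, source'); applying along both axes gives the same-space
#' covariance on the target grid, which for a symmetric input is symmetrized
#' exactly by averaging with its transpose (congruence transforms preserve
#' symmetry up to roundoff).
#'
#' @param K Kernel matrix on the operator's source grid (square for
#'   `axes = "both"`, and symmetric if a covariance).
#' @param op An [rft_operator()] whose source grid matches the axis being
#'   transformed.
#' @param axes `"both"` (congruence transform `W K W^T`) or `"rows"`
#'   (single-axis `W K`).
#' @return The transformed matrix.
#' @export
transform_kernel <- function(K, op, axes = c("both", "rows")) {
  axes <- match.arg(axes)
  stopifnot(inherits(op, "rft_operator"))
  K <- as.matrix(K)
  n <- length(op$source)
  if (nrow(K) != n) {
    stop(sprintf("transform_kernel: kernel has %d rows, operator expects %d",
                 nrow(K), n), call. = FALSE)
  }
  if (axes == "rows") return(op$weights %*% K)
  if (ncol(K) != n) {
    stop("transform_kernel: kernel must be square for axes = 'both'",
         call. = FALSE)
  }
  out <- op$weights %*% K %*% t(op$weights)
  (out + t(out)) / 2
}

#' Write an operator's weight matrix as delimited text
#'
#' Debugging export of the dense operator matrix, full double precision,
#' locale-independent.
#'
#' @param op An [rft_operator()].
#' @param path Output file path (tab-separated, no row/col names).
#' @return `path`, invisibly.
#' @export
write_rft_operator <- function(op, path) {
  stopifnot(inherits(op, "rft_operator"))
  utils::write.table(format(op$weights, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
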