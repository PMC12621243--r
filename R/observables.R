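#' Locate RDF peaks on a dense grid
#'
#' Discrete strict local maxima (greater than both neighbors) at
#' `r > search_min`, each refined to sub-grid precision by a quadratic fit
#' through the three bracketing points. `search_min` excludes the
#' bonded/excluded-volume region so that, e.g., the intramolecular H-H
#' feature is not counted as the first solvation peak.
#'
#' @param g RDF values on `r`.
#' @param r Dense radial grid (angstrom; step <= 0.01 recommended).
#' @param search_min Only maxima beyond this radius are reported (angstrom).
#' @return Tibble with columns `location`, `height`, ordered by ascending
#'   location; zero rows when no maxima exist (e.g. g identically 1).
#' @export
find_peaks <- function(g, r, search_min = 0) {
  stopifnot(length(g) == length(r))
  check_radial_grid(r)
  n <- length(g)
  if (n < 3L) return(tibble::tibble(location = numeric(), height = numeric()))
  i <- 2:(n - 1)
  is_max <- g[i] > g[i - 1] & g[i] > g[i + 1] & r[i] > search_min
  idx <- i[is_max]
  if (length(idx) == 0L) {
    return(tibble::tibble(location = numeric(), height = numeric()))
  }
  loc <- numeric(length(idx)); hei <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    ym <- g[j - 1]; y0 <- g[j]; yp <- g[j + 1]
    a <- (yp + ym - 2 * y0) / 2
    b <- (yp - ym) / 2
    h <- (r[j + 1] - r[j - 1]) / 2
    if (a < 0) {
      dx <- -b / (2 * a)
      loc[k] <- r[j] + dx * h
      hei[k] <- y0 - b^2 / (4 * a)
    } else {
      loc[k] <- r[j]; hei[k] <- y0
    }
  }
  tibble::tibble(location = loc, height = hei)
}

#' Joint statistics of the first two RDF peaks across posterior samples
#'
#' Extracts the first and second peak location/height from each posterior
#' sample, then summarizes the four quantities: marginal means and standard
#' deviations, and their Pearson correlation matrix. Samples yielding fewer
#' than two peaks are excluded and counted. Zero-variance (degenerate)
#' marginals get correlation 0 and raise the `degenerate` flag.
#'
#' @param samples Matrix of posterior draws (rows = samples) on `r`.
#' @param r Dense radial grid (angstrom).
#' @param search_min Passed to [find_peaks()].
#' @return An object of class `peak_stats`: per-sample tibble, summary
#'   tibble, correlation matrix, counts, degeneracy flag.
#' @export
peak_statistics <- function(samples, r, search_min = 0) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == length(r))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    pk <- find_peaks(samples[i, ], r, search_min)
    if (nrow(pk) < 2L) return(NULL)
    tibble::tibble(sample = i,
                   loc1 = pk$location[1], height1 = pk$height[1],
                   loc2 = pk$location[2], height2 = pk$height[2])
  })
  n_excluded <- sum(vapply(rows, is.null, logical(1)))
  per_sample <- dplyr::bind_rows(rows)
  if (nrow(per_sample) < 2L) {
    stop("peak_statistics: fewer than 2 samples with two or more peaks",
         call. = FALSE)
  }
  M <- as.matrix(per_sample[c("loc1", "height1", "loc2", "height2")])
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  degenerate <- any(sdv == 0)
  C <- diag(1, 4)
  dimnames(C) <- list(colnames(M), colnames(M))
  for (a in 1:3) for (b in (a + 1):4) {
    rho <- if (sdv[a] == 0 || sdv[b] == 0) 0 else stats::cor(M[, a], M[, b])
    C[a, b] <- C[b, a] <- rho
  }
  structure(list(
    per_sample = per_sample,
    summary = tibble::tibble(quantity = colnames(M), mean = unname(mu),
                             sd = unname(sdv)),
    correlation = C, n_used = nrow(per_sample), n_excluded = n_excluded,
    degenerate = degenerate, search_min = search_min),
    class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("<peak_stats> %d samples used, %d excluded%s\n", x$n_used,
              x$n_excluded, if (x$degenerate) " (degenerate marginals)" else ""))
  print(x$summary)
  invisible(x)
}

#' @method tidy peak_stats
#' @export
tidy.peak_stats <- function(x, ...) x$summary

#' Coordination number from an RDF
#'
#' The expected number of neighbors within `r_cut`,
#' `n(r_cut) = 4 pi rho integral_0^r_cut g(r) r^2 dr`, by trapezoid
#' quadrature with linear interpolation of g at the cutoff.
#'
#' @param g RDF values on `r`.
#' @param r Radial grid (angstrom).
#' @param density Atomic number density rho (atoms/angstrom^3).
#' @param r_cut Cutoff radius (angstrom), inside the grid range.
#' @return Coordination number (atoms).
#' @export
coordination_number <- function(g, r, density, r_cut) {
  stopifnot(length(g) == length(r), density > 0)
  check_radial_grid(r)
  if (r_cut < r[1] || r_cut > r[length(r)]) {
    stop(sprintf("r_cut = %g outside the grid range [%g, %g]",
                 r_cut, r[1], r[length(r)]), call. = FALSE)
  }
  keep <- r <= r_cut
  rr <- r[keep]; gg <- g[keep]
  if (rr[length(rr)] < r_cut) {
    gc <- stats::approx(r, g, xout = r_cut)$y
    rr <- c(rr, r_cut); gg <- c(gg, gc)
  }
  f <- gg * rr^2
  4 * pi * density * sum(diff(rr) * (f[-1] + f[-length(f)]) / 2)
}

# First local minimum strictly after the first peak (search_min applied to
# the peak search); NA when no peak or no following minimum exists.
first_min_after_peak <- function(g, r, search_min = 0) {
  pk <- find_peaks(g, r, search_min)
  if (nrow(pk) == 0L) return(NA_real_)
  n <- length(g)
  i <- 2:(n - 1)
  is_min <- g[i] < g[i - 1] & g[i] < g[i + 1] & r[i] > pk$location[1]
  idx <- i[is_min]
  if (length(idx) == 0L) return(NA_real_)
  j <- idx[1]
  ym <- g[j - 1]; y0 <- g[j]; yp <- g[j + 1]
  a <- (yp + ym - 2 * y0) / 2
  b <- (yp - ym) / 2
  h <- (r[j + 1] - r[j - 1]) / 2
  if (a > 0) r[j] - b / (2 * a) * h else r[j]
}

#' Coordination-number distribution over posterior samples
#'
#' Integrates each posterior sample of g(r) to its cutoff and histograms the
#' results. In `cutoff = "auto"` mode the per-sample cutoff is the first
#' local minimum after the first peak (samples with no such minimum are
#' excluded and counted); a numeric `cutoff` fixes one radius for all
#' samples. The integrand convention (`4 pi rho g r^2`) and cutoff rule are
#' recorded in the result.
#'
#' @param samples Matrix of posterior draws (rows = samples) on `r`.
#' @param r Radial grid (angstrom).
#' @param density Atomic number density rho (atoms/angstrom^3).
#' @param cutoff `"auto"` or a fixed radius (angstrom).
#' @param search_min Passed to the peak search in auto mode.
#' @param bins Number of histogram bins.
#' @return An object of class `coordination_result`: per-sample values and
#'   cutoffs, mean +/- sd summary, histogram, exclusion count, metadata.
#' @export
coordination_distribution <- function(samples, r, density, cutoff = "auto",
                                      search_min = 0, bins = 30) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == length(r))
  auto <- identical(cutoff, "auto")
  if (!auto) stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  ns <- nrow(samples)
  vals <- rep(NA_real_, ns); cuts <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    rc <- if (auto) first_min_after_peak(samples[i, ], r, search_min) else cutoff
    if (is.na(rc) || rc < r[1] || rc > r[length(r)]) next
    cuts[i] <- rc
    vals[i] <- coordination_number(samples[i, ], r, density, rc)
  }
  used <- !is.na(vals)
  if (!any(used)) stop("no sample yielded a usable cutoff", call. = FALSE)
  v <- vals[used]
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  hh <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                       plot = FALSE)
  structure(list(
    values = v, cutoffs = cuts[used],
    mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
    histogram = tibble::tibble(
      bin_lower = hh$breaks[-length(hh$breaks)],
      bin_upper = hh$breaks[-1], count = hh$counts),
    n_used = sum(used), n_excluded = sum(!used),
    cutoff_mode = if (auto) "first local minimum after first peak" else
      sprintf("fixed r_cut = %g A", cutoff),
    definition = "n(r_cut) = 4 pi rho int_0^r_cut g(r) r^2 dr",
    density = density), class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("<coordination_result> n = %.3f +/- %.3f atoms (%d samples, %d excluded)\n",
              x$mean, x$sd, x$n_used, x$n_excluded))
  cat("  cutoff:", x$cutoff_mode, "\n  definition:", x$definition, "\n")
  invisible(x)
}

#' @method tidy coordination_result
#' @export
tidy.coordination_result <- function(x, ...) x$histogram

#' @method glance coordination_result
#' @export
glance.coordination_result <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n_used = x$n_used,
                 n_excluded = x$n_excluded, cutoff_mode = x$cutoff_mode)
}
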