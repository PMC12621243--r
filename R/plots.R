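#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a posterior band
#'
#' Mean with a credible ribbon; for q-space posteriors of a fit, overlay the
#' observations with [plot_fit()].
#'
#' @param object An `rdf_posterior`.
#' @param level Band level (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdf_posterior
#' @export
autoplot.rdf_posterior <- function(object, level = 0.95, ...) {
  tb <- tidy(object, level = level)
  xvar <- names(tb)[1]
  xlab <- if (xvar == "r") "r [Å]" else "q [1/Å]"
  ylab <- if (xvar == "r") "g(r)" else "S(q)"
  ggplot2::ggplot(tb, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("%s-space posterior%s", object$space,
                                  if (isTRUE(object$noise_free))
                                    " (noise-free)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot a fit against its data
#'
#' q-space posterior band overlaid on the observed structure factor.
#'
#' @param fit An `rdf_gp` object.
#' @param level Band level.
#' @return A ggplot object.
#' @export
plot_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rdf_gp"))
  post <- posterior_q(fit, fit$data$q)
  autoplot(post, level = level) +
    ggplot2::geom_point(data = tibble::tibble(q = fit$data$q, S = fit$data$S),
                        ggplot2::aes(x = .data$q, y = .data$S),
                        inherit.aes = FALSE, size = 0.5, alpha = 0.5)
}

#' @method autoplot rdf_gp
#' @export
autoplot.rdf_gp <- function(object, level = 0.95, ...) plot_fit(object, level)

#' Histogram plot of a coordination-number distribution
#'
#' @param object A `coordination_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coordination_result
#' @export
autoplot.coordination_result <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$histogram$bin_upper[1] -
                        object$histogram$bin_lower[1],
                      fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "coordination number [atoms]", y = "samples") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
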