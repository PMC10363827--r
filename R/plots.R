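#' Plot a fitted delivery-rate curve
#'
#' Observed per-interval counts with the posterior-mean expected-count
#' curve and a 95% credible ribbon evaluated on a fine grid.
#'
#' @param object An `owl_delivery_fit`.
#' @param n_grid Grid resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot owl_delivery_fit
#' @export
autoplot.owl_delivery_fit <- function(object, n_grid = 100, ...) {
  grid <- seq(object$delta0, object$delta2, length.out = n_grid)
  draws <- do.call(rbind, object$chains)
  curves <- vapply(seq_len(nrow(draws)), function(i) {
    exp(piecewise_log_rate(grid, draws[i, "delta1"], draws[i, "beta1"],
                           draws[i, "beta2"], object$delta0, object$delta2))
  }, numeric(length(grid)))
  band <- tibble(
    x = grid,
    fit = rowMeans(curves),
    lo = apply(curves, 1, quantile, 0.025),
    hi = apply(curves, 1, quantile, 0.975))
  ggplot2::ggplot(band, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$x, y = .data$y), alpha = 0.3) +
    ggplot2::labs(x = object$x_axis, y = "prey deliveries per 15 min")
}

#' Plot the population nestling-growth curve
#'
#' Observed masses with the population-level piecewise growth curve at the
#' posterior means of the hyperparameters.
#'
#' @param object An `owl_growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot owl_growth_fit
#' @export
autoplot.owl_growth_fit <- function(object, ...) {
  s <- object$summary
  val <- function(p) s$mean[s$term == p]
  grid <- seq(object$age_range[1], object$age_range[2], length.out = 100)
  mu <- val("mu_alpha") + val("mu_b1") * pmin(grid, val("mu_delta")) +
    (grid > val("mu_delta")) * val("mu_b2") * (grid - val("mu_delta"))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$mass_g)) +
    ggplot2::geom_point(alpha = 0.2) +
    ggplot2::geom_line(data = tibble(age = grid, mass_g = mu), linewidth = 1) +
    ggplot2::geom_vline(xintercept = val("mu_delta"), linetype = 2) +
    ggplot2::labs(x = "nestling age (days)", y = "mass (g)")
}

#' Trace plot of posterior draws
#'
#' @param fit An `owl_posterior`.
#' @param pars Parameters to show (default: all, capped at 9).
#' @return A ggplot faceted by parameter, coloured by chain.
#' @export
plot_trace <- function(fit, pars = NULL) {
  d <- posterior_draws(fit)
  keep <- pars %||% utils::head(setdiff(names(d), c("chain", "iteration")), 9)
  long <- tidyr::pivot_longer(d, all_of(keep), names_to = "term")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(colour = "chain")
}

#' Posterior category means from a productivity fit
#'
#' Density display of the posterior distributions of the two category
#' means (reference and contrast), the basis of the CRI-overlap
#' comparison.
#'
#' @param fit An `owl_productivity_fit`.
#' @return A ggplot.
#' @export
plot_productivity_means <- function(fit) {
  d <- posterior_draws(fit) %>%
    select("mean_ref", "mean_alt") %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "category")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, fill = .data$category)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "posterior category mean (count)", y = "density")
}
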