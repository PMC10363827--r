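#' Two-segment log-linear rate
#'
#' Log expected delivery count per 15-min interval under the joined
#' two-segment changepoint model. With domain origin `delta0` (fixed at 0),
#' changepoint `delta1` and domain maximum `delta2`,
#' `log rate = beta1 * (min(x, delta1) - delta0) +
#'             I(x > delta1) * beta2 * (min(x, delta2) - delta1)`.
#' The curve is continuous at `delta1` and the model has a zero intercept:
#' the expected count at `x = delta0` is exactly `exp(0) = 1`, since
#' deliveries do not occur before sunset or before hatching.
#'
#' @param x Predictor (minutes after sunset, or nestling age in days);
#'   vectorised, must lie in `[delta0, delta2]`.
#' @param delta1 Changepoint, in the units of `x`.
#' @param beta1,beta2 Segment slopes on the log scale, per unit `x`.
#' @param delta0 Domain origin (fixed 0).
#' @param delta2 Domain maximum (fixed at the largest observed `x`).
#' @return Log expected count, same length as `x`.
#' @export
#' @examples
#' piecewise_log_rate(60, delta1 = 37.85, beta1 = 0.05, beta2 = -0.02,
#'                    delta2 = 90)
piecewise_log_rate <- function(x, delta1, beta1, beta2, delta0 = 0,
                               delta2 = max(x)) {
  stopifnot(delta0 <= delta1, delta1 <= delta2)
  if (any(x < delta0 | x > delta2)) abort("x outside [delta0, delta2]")
  beta1 * (pmin(x, delta1) - delta0) +
    (x > delta1) * beta2 * (pmin(x, delta2) - delta1)
}

#' Fit the Bayesian delivery-rate changepoint model
#'
#' Total per-interval delivery counts (male + female + unknown) are
#' modelled as `y_i ~ Poisson(exp(piecewise_log_rate(x_i)))` with a single
#' changepoint, zero intercept and log link. Priors: changepoint uniform
#' between the minimum and maximum observed `x`; slopes normal with mean 0
#' and variance 1000. Fit one model per weather category (wet, dry, warm,
#' cold) by subsetting `obs` before calling.
#'
#' @param obs Filtered delivery-observation tibble (>= 10 intervals,
#'   >= 3 distinct `x` values).
#' @param x_axis `"minutes_after_sunset"` (nightly model) or
#'   `"nest_age_days"` (seasonal model).
#' @param config A [chain_config()]; the reference settings are three
#'   chains of 20,000 iterations with 4,000 burn-in.
#' @return An `owl_delivery_fit` / `owl_posterior` with parameters
#'   `delta1`, `beta1`, `beta2`; the data and domain are attached for
#'   [rate_curve_summaries()] and [autoplot()].
#' @export
fit_delivery_changepoint <- function(obs,
                                     x_axis = c("minutes_after_sunset", "nest_age_days"),
                                     config = chain_config()) {
  x_axis <- match.arg(x_axis)
  x <- obs[[x_axis]]
  y <- obs$n_male + obs$n_female + obs$n_unknown
  stopifnot(length(y) >= 10, length(unique(x)) >= 3, all(y >= 0))
  d0 <- 0
  d2 <- max(x)
  lo <- min(x)

  loglik <- function(theta) {
    sum(dpois(y, exp(piecewise_log_rate(x, theta["delta1"], theta["beta1"],
                                        theta["beta2"], d0, d2)), log = TRUE))
  }
  # profile-ML start keeps burn-in short; does not affect the target
  grid <- seq(lo + 0.05 * (d2 - lo), d2 - 0.05 * (d2 - lo), length.out = 12)
  ml <- changepoint_profile_oracle(x, y, grid, delta0 = d0, delta2 = d2)
  init <- c(delta1 = ml$delta1, beta1 = ml$beta1,
            beta2 = ifelse(is.na(ml$beta2), 0, ml$beta2))

  priors <- list(delta1 = prior_uniform(lo, d2),
                 beta1 = prior_normal(0, 1000),
                 beta2 = prior_normal(0, 1000))
  fit <- sample_posterior(loglik, priors, config, init = init)
  fit$model <- "delivery"
  fit$x_axis <- x_axis
  fit$data <- tibble(x = x, y = y)
  fit$delta0 <- d0
  fit$delta2 <- d2
  class(fit) <- c("owl_delivery_fit", "owl_posterior")
  fit
}

#' Posterior summaries of the fitted rate curve
#'
#' For each retained posterior draw, evaluates the expected count on a
#' grid of predictor values and records the curve's mean, minimum and
#' maximum; each functional is then summarised by its posterior mean and
#' 95% credible interval. The default grid is the sorted unique observed
#' predictor values.
#'
#' @param fit An `owl_delivery_fit`.
#' @param x_grid Grid of predictor values (non-empty).
#' @return Tibble with rows `mean`, `min`, `max` and columns `estimate`,
#'   `cri_lo`, `cri_hi`.
#' @export
rate_curve_summaries <- function(fit, x_grid = sort(unique(fit$data$x))) {
  stopifnot(inherits(fit, "owl_delivery_fit"))
  if (length(x_grid) == 0) abort("empty x grid")
  draws <- do.call(rbind, fit$chains)
  d1 <- draws[, "delta1"]; b1 <- draws[, "beta1"]; b2 <- draws[, "beta2"]
  m <- length(x_grid); n <- length(d1)
  # grid x draws matrix of expected counts
  xm <- outer(x_grid, d1, pmin)                       # min(x, delta1)
  seg2 <- outer(x_grid, d1, `>`) *
    (matrix(pmin(x_grid, fit$delta2), m, n) - matrix(d1, m, n, byrow = TRUE))
  rate <- exp(sweep(xm - fit$delta0, 2, b1, `*`) + sweep(seg2, 2, b2, `*`))
  per_draw <- tibble(mean = colMeans(rate),
                     min = apply(rate, 2, min),
                     max = apply(rate, 2, max))
  purrr::map_dfr(c("mean", "min", "max"), function(f) {
    v <- per_draw[[f]]
    ci <- credible_interval(v)
    tibble(functional = f, estimate = mean(v), cri_lo = ci[1], cri_hi = ci[2])
  })
}

#' Profile-likelihood changepoint oracle
#'
#' Independent maximum-likelihood cross-check for the Bayesian changepoint
#' fit: for each candidate changepoint on a grid, the two slopes are fit by
#' a zero-intercept Poisson GLM (log link) on the segment covariates, and
#' the grid point maximising the profile log-likelihood is returned. Ties
#' break to the smallest grid value.
#'
#' @param x,y Predictor and count vectors.
#' @param grid Candidate changepoints within the data range.
#' @param delta0,delta2 Domain endpoints.
#' @return List with `delta1`, `beta1`, `beta2`, `log_lik`, and the full
#'   `profile` tibble.
#' @export
changepoint_profile_oracle <- function(x, y, grid, delta0 = 0, delta2 = max(x)) {
  stopifnot(all(grid >= delta0), all(grid <= delta2), length(grid) >= 1)
  grid <- sort(grid)
  prof <- purrr::map_dfr(grid, function(d1) {
    x1 <- pmin(x, d1) - delta0
    x2 <- (x > d1) * (pmin(x, delta2) - d1)
    if (all(x2 == 0)) {
      fit <- glm(y ~ 0 + x1, family = poisson())
      tibble(delta1 = d1, beta1 = unname(coef(fit)[1]), beta2 = NA_real_,
             log_lik = as.numeric(logLik(fit)))
    } else {
      fit <- glm(y ~ 0 + x1 + x2, family = poisson())
      tibble(delta1 = d1, beta1 = unname(coef(fit)["x1"]),
             beta2 = unname(coef(fit)["x2"]),
             log_lik = as.numeric(logLik(fit)))
    }
  })
  best <- prof[which.max(prof$log_lik), ]
  list(delta1 = best$delta1, beta1 = best$beta1, beta2 = best$beta2,
       log_lik = best$log_lik, profile = prof)
}
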