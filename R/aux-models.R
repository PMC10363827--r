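#' Per-interval female share of sexed deliveries
#'
#' Converts delivery observations into division-of-labor records: the
#' proportion of sexed deliveries made by the female in each interval,
#' `p = n_female / (n_female + n_male)`. Unknown-sex deliveries are
#' excluded; intervals with no sexed delivery are dropped. Because a beta
#' likelihood has no mass at 0 or 1, proportions are compressed with the
#' Smithson-Verkuilen squeeze `p' = (p * (N - 1) + 0.5) / N`, where `N` is
#' the total number of sexed deliveries in the dataset.
#'
#' @param obs Delivery-observation tibble.
#' @param x_axis Predictor column carried along: `"minutes_after_sunset"`
#'   or `"nest_age_days"`.
#' @return Tibble: `nest_id`, `x`, `p_female` (squeezed), `n_sexed`.
#' @export
#' @examples
#' obs <- tibble::tibble(nest_id = "n1", minutes_after_sunset = 30,
#'                       nest_age_days = 10, n_male = 3, n_female = 1,
#'                       n_unknown = 2)
#' female_proportion(obs)
female_proportion <- function(obs,
                              x_axis = c("minutes_after_sunset", "nest_age_days")) {
  x_axis <- match.arg(x_axis)
  n_sexed <- obs$n_male + obs$n_female
  keep <- n_sexed >= 1
  big_n <- sum(n_sexed[keep])
  p <- obs$n_female[keep] / n_sexed[keep]
  tibble(nest_id = obs$nest_id[keep],
         x = obs[[x_axis]][keep],
         p_female = (p * (big_n - 1) + 0.5) / big_n,
         n_sexed = n_sexed[keep])
}

#' Fit the division-of-labor beta GLM
#'
#' Bayesian beta regression of the per-interval female share of sexed
#' deliveries on time after sunset or nestling age:
#' `logit(mu_i) = b0 + b1 * x_i`, `p_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)`
#' with precision `phi`. Priors: `b0`, `b1` normal(0, 1000); `phi`
#' half-normal(0, 31.6). Run once per weather category; significance of
#' between-category differences is judged by credible-interval overlap.
#'
#' @param data Output of [female_proportion()] (>= 10 rows).
#' @param config A [chain_config()]; reference settings are three chains of
#'   10,000 iterations with 1,000 burn-in.
#' @param weight_by_n If `TRUE`, each interval's log-likelihood is weighted
#'   by its number of sexed deliveries (default: one interval, one point).
#' @return An `owl_labor_fit` / `owl_posterior` with terms `b0`, `b1`,
#'   `phi`.
#' @export
fit_labor_beta <- function(data, config = chain_config(3, 10000, 1000),
                           weight_by_n = FALSE) {
  stopifnot(nrow(data) >= 10, all(data$p_female > 0 & data$p_female < 1))
  x <- data$x
  p <- data$p_female
  w <- if (weight_by_n) data$n_sexed else rep(1, length(p))
  loglik <- function(th) {
    mu <- plogis(th["b0"] + th["b1"] * x)
    sum(w * dbeta(p, mu * th["phi"], (1 - mu) * th["phi"], log = TRUE))
  }
  priors <- list(b0 = prior_normal(0, 1000), b1 = prior_normal(0, 1000),
                 phi = prior_half_normal(31.6))
  fit <- sample_posterior(loglik, priors, config,
                          init = c(b0 = qlogis(mean(p)), b1 = 0, phi = 5))
  fit$model <- "labor"
  fit$data <- tibble(x = x, p_female = p)
  class(fit) <- c("owl_labor_fit", "owl_posterior")
  fit
}

#' Fit the adult-mass trend mixed model
#'
#' Bayesian Gaussian mixed model of adult mass on Julian day, run
#' separately per sex and per weather category:
#' `mass_ij = (a + u_j) + (b + v_j) * julian_ij + e_ij`, with random
#' intercepts `u_j` and slopes `v_j` by band and `e_ij ~ N(0, sigma^2)`.
#' Fixed-effect priors are normal(0, 1000); random-effect sds are
#' half-normal(0, 31.6) and the residual sd half-normal(0, 100). A
#' significant mass trend means the fixed slope's 95% CRI excludes zero.
#' Individuals captured once still inform the intercepts; their slopes
#' shrink to the population mean.
#'
#' The sampler works on day values centred at their mean (an exact
#' reparameterisation that decorrelates intercepts and slopes) and reports
#' intercepts back on the raw Julian-day scale unless `centre = TRUE`.
#'
#' @param masses Mass-record tibble; rows with `cohort == cohort` are used.
#' @param cohort `"adult_female"` or `"adult_male"`.
#' @param config A [chain_config()]; reference settings are three chains of
#'   200,000 iterations with 50,000 burn-in.
#' @param centre Report intercepts at the mean Julian day instead of day 0.
#' @return An `owl_mass_fit` / `owl_posterior` with terms `intercept`,
#'   `slope`, `sd_intercept`, `sd_slope`, `sigma_resid`.
#' @export
fit_mass_trend <- function(masses, cohort = c("adult_female", "adult_male"),
                           config = chain_config(3, 200000, 50000),
                           centre = FALSE) {
  cohort <- match.arg(cohort)
  d <- masses[masses$cohort == cohort, , drop = FALSE]
  bands <- sort(unique(d$band_id))
  J <- length(bands)
  stopifnot(J >= 5)
  g <- match(d$band_id, bands)
  cbar <- mean(d$julian_day)
  xc <- d$julian_day - cbar
  y <- d$mass_g

  gss <- function(mu) rowsum((y - mu)^2, g)[, 1]
  base_fit <- glm(y ~ xc)
  cf <- coef(base_fit)

  par_names <- c("intercept", "slope", "sd_intercept", "sd_slope", "sigma_resid")
  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  chains <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    alpha <- rep(cf[1], J) + rnorm(J, 0, 0.5)
    beta <- rep(cf[2], J) + rnorm(J, 0, 0.01)
    a <- mean(alpha); b <- mean(beta)
    sd_u <- 1; sd_v <- 0.05
    sigma <- max(sd(base_fit$residuals), 0.1)
    mu_vec <- alpha[g] + beta[g] * xc

    sc <- c(alpha = 0.5, beta = 0.02, sd_u = 0.3, sd_v = 0.02, sigma = 0.1)
    acc <- sc * 0; tries <- sc * 0

    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    kept <- 0L

    for (it in seq_len(config$n_iterations)) {
      prop <- alpha + sc["alpha"] * rnorm(J)
      new_mu <- mu_vec + (prop - alpha)[g]
      dll <- (gss(mu_vec) - gss(new_mu)) / (2 * sigma^2)
      dlp <- dnorm(prop, a, sd_u, log = TRUE) - dnorm(alpha, a, sd_u, log = TRUE)
      ok <- log(runif(J)) < dll + dlp
      tries["alpha"] <- tries["alpha"] + 1; acc["alpha"] <- acc["alpha"] + mean(ok)
      alpha <- ifelse(ok, prop, alpha)
      mu_vec <- alpha[g] + beta[g] * xc

      prop <- beta + sc["beta"] * rnorm(J)
      new_mu <- mu_vec + (prop - beta)[g] * xc
      dll <- (gss(mu_vec) - gss(new_mu)) / (2 * sigma^2)
      dlp <- dnorm(prop, b, sd_v, log = TRUE) - dnorm(beta, b, sd_v, log = TRUE)
      ok <- log(runif(J)) < dll + dlp
      tries["beta"] <- tries["beta"] + 1; acc["beta"] <- acc["beta"] + mean(ok)
      beta <- ifelse(ok, prop, beta)
      mu_vec <- alpha[g] + beta[g] * xc

      draw_mu <- function(vals, s) {
        v <- 1 / (J / s^2 + 1 / 1000)
        rnorm(1, v * sum(vals) / s^2, sqrt(v))
      }
      a <- draw_mu(alpha, sd_u); b <- draw_mu(beta, sd_v)

      sd_step <- function(cur, vals, mu, key, prior_sd) {
        prop <- reflect_into(cur + sc[key] * rnorm(1), 1e-6, Inf)
        dll <- sum(dnorm(vals, mu, prop, log = TRUE)) -
               sum(dnorm(vals, mu, cur, log = TRUE))
        dlp <- dnorm(prop, 0, prior_sd, log = TRUE) - dnorm(cur, 0, prior_sd, log = TRUE)
        tries[key] <<- tries[key] + 1
        if (log(runif(1)) < dll + dlp) { acc[key] <<- acc[key] + 1; prop } else cur
      }
      sd_u <- sd_step(sd_u, alpha, a, "sd_u", 31.6)
      sd_v <- sd_step(sd_v, beta, b, "sd_v", 31.6)
      sigma <- sd_step(sigma, y, mu_vec, "sigma", 100)

      if (it <= config$n_burnin && it %% 50L == 0L) {
        sc <- sc * exp(acc / pmax(tries, 1) - 0.38)
        acc[] <- 0; tries[] <- 0
      }
      if (it > config$n_burnin && (it - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        icpt <- if (centre) a else a - b * cbar
        draws[kept, ] <- c(icpt, b, sd_u, sd_v, sigma)
      }
    }
    chains[[ch]] <- draws[seq_len(kept), , drop = FALSE]
  }

  fit <- new_owl_posterior(chains, config, model = "mass",
                           extra = list(cohort = cohort, centre = centre,
                                        julian_mean = cbar,
                                        data = tibble(band_id = d$band_id,
                                                      julian_day = d$julian_day,
                                                      mass_g = y)))
  fit
}

#' Fit the productivity Poisson GLM
#'
#' Bayesian Poisson regression of a productivity count (clutch, brood or
#' fledglings) on a binary weather-category indicator:
#' `value_i ~ Poisson(exp(c0 + c1 * indicator_i))`, priors normal(0, 1000).
#' The effect `c1` is significant if its 95% CRI excludes zero; the
#' posterior distributions of the two category means `exp(c0)` and
#' `exp(c0 + c1)` are returned as derived parameters for overlap displays.
#'
#' @param data Tibble with `value` (count) and `category_indicator`
#'   (0 = reference category, 1 = contrast category); >= 10 nests per
#'   category.
#' @param config A [chain_config()]; reference settings are three chains of
#'   20,000 iterations with 4,000 burn-in.
#' @return An `owl_productivity_fit` / `owl_posterior` with terms `c0`,
#'   `c1`, `mean_ref`, `mean_alt`.
#' @export
fit_productivity <- function(data, config = chain_config(3, 20000, 4000)) {
  y <- data$value
  ind <- data$category_indicator
  stopifnot(all(y >= 0), all(ind %in% c(0, 1)),
            sum(ind == 0) >= 10, sum(ind == 1) >= 10)
  for (k in c(0, 1)) {
    if (all(y[ind == k] == 0))
      inform(paste0("all counts zero in category ", k,
                    "; the effect posterior is prior-dominated"))
  }
  loglik <- function(th) sum(dpois(y, exp(th["c0"] + th["c1"] * ind), log = TRUE))
  priors <- list(c0 = prior_normal(0, 1000), c1 = prior_normal(0, 1000))
  init <- c(c0 = log(max(mean(y[ind == 0]), 0.05)),
            c1 = log(max(mean(y[ind == 1]), 0.05)) -
                 log(max(mean(y[ind == 0]), 0.05)))
  fit <- sample_posterior(loglik, priors, config, init = init)
  chains <- lapply(fit$chains, function(m) {
    cbind(m, mean_ref = exp(m[, "c0"]), mean_alt = exp(m[, "c0"] + m[, "c1"]))
  })
  out <- new_owl_posterior(chains, config, model = "productivity",
                           extra = list(data = tibble(value = y,
                                                      category_indicator = ind)))
  out
}
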