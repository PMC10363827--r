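#' Fit the hierarchical nestling-growth changepoint model
#'
#' Gaussian mixed-effects growth model with a per-nestling changepoint:
#' `mass_ij = alpha_j + b1_j * min(age_ij, delta_j) +
#'            I(age_ij > delta_j) * b2_j * (age_ij - delta_j) + e_ij`,
#' `e_ij ~ N(0, sigma_resid^2)`. The model includes an intercept because
#' owlets have nonzero mass at hatching, and the intercept, both slopes and
#' the changepoint all vary by nestling, drawn from population-level
#' normals; the population changepoint mean has a uniform prior over the
#' observed age range, the other population means are normal(0, 1000), the
#' population sds are half-normal(0, 31.6) and the residual sd is
#' half-normal(0, 100).
#'
#' Sampling is Metropolis-within-Gibbs: all per-nestling parameters of one
#' kind are proposed jointly and accepted per nestling (they are
#' conditionally independent given the hyperparameters), population means
#' are drawn from their conjugate normal conditionals, and the scale
#' parameters use reflected random-walk steps. Proposal scales adapt
#' during burn-in.
#'
#' @param masses Mass-record tibble; only `cohort == "nestling"` rows are
#'   used. Nestlings with fewer than two measurements are excluded with a
#'   warning (>= 5 nestlings required after exclusion).
#' @param config A [chain_config()]; the reference settings are three
#'   chains of 4,000 iterations with 2,000 burn-in.
#' @return An `owl_growth_fit` / `owl_posterior`. Hyperparameters are
#'   `mu_alpha`, `mu_b1`, `mu_b2`, `mu_delta`, `sd_alpha`, `sd_b1`,
#'   `sd_b2`, `sd_delta`, `sigma_resid`; per-nestling parameters are named
#'   `alpha[band]` etc.
#' @export
fit_growth_hierarchical <- function(masses, config = chain_config(3, 4000, 2000)) {
  d <- masses %>% filter(.data$cohort == "nestling")
  counts <- table(d$band_id)
  few <- names(counts)[counts < 2]
  if (length(few) > 0) {
    warn(paste0("excluding ", length(few), " nestling(s) with < 2 measurements"))
    d <- d %>% filter(!.data$band_id %in% few)
  }
  bands <- sort(unique(d$band_id))
  J <- length(bands)
  stopifnot(J >= 5)
  g <- match(d$band_id, bands)
  age <- d$nestling_age_days
  y <- d$mass_g
  lo <- min(age); hi <- max(age)

  pred <- function(alpha, b1, b2, delta) {
    alpha[g] + b1[g] * pmin(age, delta[g]) +
      (age > delta[g]) * b2[g] * pmax(age - delta[g], 0)
  }
  # per-group -0.5 * sum sq residuals
  gss <- function(mu) rowsum((y - mu)^2, g)[, 1]

  mid <- (lo + hi) / 2
  start_fit <- glm(y ~ I(pmin(age, mid)) + I(pmax(age - mid, 0)))
  cf <- coef(start_fit)

  hyper_names <- c("mu_alpha", "mu_b1", "mu_b2", "mu_delta",
                   "sd_alpha", "sd_b1", "sd_b2", "sd_delta", "sigma_resid")
  par_names <- c(hyper_names,
                 paste0("alpha[", bands, "]"), paste0("b1[", bands, "]"),
                 paste0("b2[", bands, "]"), paste0("delta[", bands, "]"))
  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  chains <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    alpha <- rep(cf[1], J) + rnorm(J, 0, 0.5)
    b1 <- rep(cf[2], J) + rnorm(J, 0, 0.05)
    b2 <- rep(cf[3], J) + rnorm(J, 0, 0.05)
    delta <- runif(J, mid - 0.15 * (hi - lo), mid + 0.15 * (hi - lo))
    mu_a <- mean(alpha); mu_b1 <- mean(b1); mu_b2 <- mean(b2); mu_d <- mean(delta)
    sd_a <- 1; sd_b1 <- 0.3; sd_b2 <- 0.3; sd_d <- 1.5
    sigma <- max(sd(start_fit$residuals), 0.1)
    mu_vec <- pred(alpha, b1, b2, delta)

    sc <- c(alpha = 0.5, b1 = 0.1, b2 = 0.1, delta = 1,
            sd_a = 0.3, sd_b1 = 0.1, sd_b2 = 0.1, sd_d = 0.3, sigma = 0.1)
    acc <- sc * 0; tries <- sc * 0

    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    kept <- 0L

    vec_update <- function(cur, prop, new_mu, prior_mu, prior_sd, which) {
      dll <- (gss(mu_vec) - gss(new_mu)) / (2 * sigma^2)
      dlp <- dnorm(prop, prior_mu, prior_sd, log = TRUE) -
             dnorm(cur, prior_mu, prior_sd, log = TRUE)
      a <- log(runif(J)) < dll + dlp
      tries[which] <<- tries[which] + 1
      acc[which] <<- acc[which] + mean(a)
      list(val = ifelse(a, prop, cur), acc = a)
    }

    for (it in seq_len(config$n_iterations)) {
      # --- per-nestling parameters, vectorised over nestlings
      prop <- alpha + sc["alpha"] * rnorm(J)
      up <- vec_update(alpha, prop, mu_vec + (prop - alpha)[g], mu_a, sd_a, "alpha")
      mu_vec <- mu_vec + (up$val - alpha)[g]
      alpha <- up$val

      prop <- b1 + sc["b1"] * rnorm(J)
      new_mu <- mu_vec + (prop - b1)[g] * pmin(age, delta[g])
      up <- vec_update(b1, prop, new_mu, mu_b1, sd_b1, "b1")
      mu_vec <- mu_vec + (up$val - b1)[g] * pmin(age, delta[g])
      b1 <- up$val

      prop <- b2 + sc["b2"] * rnorm(J)
      x2 <- (age > delta[g]) * pmax(age - delta[g], 0)
      up <- vec_update(b2, prop, mu_vec + (prop - b2)[g] * x2, mu_b2, sd_b2, "b2")
      mu_vec <- mu_vec + (up$val - b2)[g] * x2
      b2 <- up$val

      prop <- reflect_into(delta + sc["delta"] * rnorm(J), lo, hi)
      new_delta <- prop
      new_mu <- pred(alpha, b1, b2, new_delta)
      up <- vec_update(delta, prop, new_mu, mu_d, sd_d, "delta")
      delta <- up$val
      mu_vec <- pred(alpha, b1, b2, delta)

      # --- conjugate draws for population means
      draw_mu <- function(vals, s) {
        v <- 1 / (J / s^2 + 1 / 1000)
        rnorm(1, v * sum(vals) / s^2, sqrt(v))
      }
      mu_a <- draw_mu(alpha, sd_a); mu_b1 <- draw_mu(b1, sd_b1)
      mu_b2 <- draw_mu(b2, sd_b2)
      # uniform(lo, hi) prior on the population changepoint -> truncated normal
      v <- sd_d^2 / J; m0 <- mean(delta)
      pl <- pnorm(lo, m0, sqrt(v)); ph <- pnorm(hi, m0, sqrt(v))
      mu_d <- qnorm(runif(1, pl, ph), m0, sqrt(v))

      # --- random-walk steps for scales (reflected at zero)
      sd_step <- function(cur, vals, mu, scale_key, prior_sd) {
        prop <- reflect_into(cur + sc[scale_key] * rnorm(1), 1e-6, Inf)
        dll <- sum(dnorm(vals, mu, prop, log = TRUE)) -
               sum(dnorm(vals, mu, cur, log = TRUE))
        dlp <- dnorm(prop, 0, prior_sd, log = TRUE) - dnorm(cur, 0, prior_sd, log = TRUE)
        tries[scale_key] <<- tries[scale_key] + 1
        if (log(runif(1)) < dll + dlp) { acc[scale_key] <<- acc[scale_key] + 1; prop } else cur
      }
      sd_a <- sd_step(sd_a, alpha, mu_a, "sd_a", 31.6)
      sd_b1 <- sd_step(sd_b1, b1, mu_b1, "sd_b1", 31.6)
      sd_b2 <- sd_step(sd_b2, b2, mu_b2, "sd_b2", 31.6)
      sd_d <- sd_step(sd_d, delta, mu_d, "sd_d", 31.6)
      sigma <- sd_step(sigma, y, mu_vec, "sigma", 100)

      if (it <= config$n_burnin && it %% 50L == 0L) {
        sc <- sc * exp(acc / pmax(tries, 1) - 0.38)
        acc[] <- 0; tries[] <- 0
      }
      if (it > config$n_burnin && (it - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(mu_a, mu_b1, mu_b2, mu_d, sd_a, sd_b1, sd_b2, sd_d,
                           sigma, alpha, b1, b2, delta)
      }
    }
    chains[[ch]] <- draws[seq_len(kept), , drop = FALSE]
  }

  fit <- new_owl_posterior(chains, config, model = "growth",
                           extra = list(bands = bands,
                                        data = tibble(band_id = d$band_id,
                                                      age = age, mass_g = y),
                                        age_range = c(lo, hi)))
  fit
}
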