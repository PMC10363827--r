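#' MCMC chain configuration
#'
#' Bundles the chain settings shared by all model-fitting functions. The
#' defaults mirror the delivery-rate models (three chains of 20,000
#' iterations with a 4,000-iteration burn-in and no thinning); other model
#' families pass their own settings.
#'
#' @param n_chains Number of independent chains (>= 2 so that the
#'   Gelman-Rubin diagnostic is defined).
#' @param n_iterations Total iterations per chain, including burn-in.
#' @param n_burnin Iterations discarded from the start of each chain.
#'   Proposal scales are adapted only during burn-in.
#' @param thin Retention interval for post-burn-in draws.
#' @param seed Integer seed; every chain derives its own stream from it, so
#'   a run is reproducible bit-for-bit given the same data and config.
#'
#' @return A `chain_config` list.
#' @export
#' @examples
#' chain_config(n_iterations = 2000, n_burnin = 500, seed = 42)
chain_config <- function(n_chains = 3, n_iterations = 20000, n_burnin = 4000,
                         thin = 1, seed = 1) {
  stopifnot(n_chains >= 2, n_burnin < n_iterations, thin >= 1)
  structure(
    list(n_chains = as.integer(n_chains),
         n_iterations = as.integer(n_iterations),
         n_burnin = as.integer(n_burnin),
         thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "chain_config"
  )
}

#' Prior specifications
#'
#' Constructors for the prior families used across the models: a normal
#' prior parameterised by mean and *variance* (the wide normal(0, 1000)
#' default corresponds to sd ~ 31.6), a uniform prior with hard bounds
#' (proposals are reflected at the bounds), and a half-normal prior for
#' scale parameters.
#'
#' @param mean,variance Normal prior mean and variance.
#' @param lo,hi Uniform prior bounds, `lo < hi`.
#' @param sd Half-normal scale.
#' @return A `prior_spec` list with `logd`, `init`, `lo`, `hi` fields.
#' @export
prior_normal <- function(mean = 0, variance = 1000) {
  stopifnot(variance > 0)
  s <- sqrt(variance)
  structure(list(kind = "normal", mean = mean, sd = s,
                 logd = function(x) dnorm(x, mean, s, log = TRUE),
                 init = function() mean + rnorm(1, 0, min(s, 1)),
                 lo = -Inf, hi = Inf),
            class = "prior_spec")
}

#' @rdname prior_normal
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(lo < hi)
  structure(list(kind = "uniform", lo = lo, hi = hi,
                 logd = function(x) ifelse(x >= lo & x <= hi, -log(hi - lo), -Inf),
                 init = function() runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))),
            class = "prior_spec")
}

#' @rdname prior_normal
#' @export
prior_half_normal <- function(sd = 31.6) {
  stopifnot(sd > 0)
  structure(list(kind = "half_normal", sd = sd,
                 logd = function(x) ifelse(x > 0, dnorm(x, 0, sd, log = TRUE) + log(2), -Inf),
                 init = function() abs(rnorm(1, 0, sd / 10)) + 1e-3,
                 lo = 0, hi = Inf),
            class = "prior_spec")
}

# Reflect a proposal into (lo, hi); preserves proposal symmetry.
reflect_into <- function(x, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(x)
  if (is.finite(lo) && is.finite(hi)) {
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    y <- ifelse(y > span, 2 * span - y, y)
    return(lo + y)
  }
  if (is.finite(lo)) return(lo + abs(x - lo))
  hi - abs(x - hi)
}

#' Sample a posterior by adaptive random-walk Metropolis
#'
#' Generic posterior sampler used by all the low-dimensional models in the
#' package. Parameters are updated one at a time (Metropolis-within-Gibbs)
#' with gaussian proposals whose scales are tuned during burn-in towards an
#' acceptance rate of ~0.44; proposals for bounded parameters are reflected
#' at the prior bounds. Chains are seeded deterministically from
#' `config$seed`.
#'
#' @param log_density Function taking a named numeric parameter vector and
#'   returning the log-likelihood (finite at the initial values).
#' @param priors Named list of [prior_normal()] / [prior_uniform()] /
#'   [prior_half_normal()] specs, one per parameter.
#' @param config A [chain_config()].
#' @param init Optional named numeric vector of starting values (recycled
#'   across chains with per-chain jitter).
#'
#' @return An `owl_posterior` object: retained draws per chain, a summary
#'   tibble (posterior mean, 95% equal-tailed credible interval,
#'   Gelman-Rubin R-hat per parameter), and any convergence warnings.
#'   R-hat >= 1.1 adds a warning to the object; it never throws.
#' @export
sample_posterior <- function(log_density, priors, config = chain_config(),
                             init = NULL) {
  stopifnot(inherits(config, "chain_config"), length(priors) >= 1)
  pars <- names(priors)
  if (is.null(pars) || any(pars == "")) abort("priors must be a named list")
  npar <- length(pars)
  lo <- vapply(priors, function(p) p$lo %||% -Inf, numeric(1))
  hi <- vapply(priors, function(p) p$hi %||% Inf, numeric(1))

  log_post <- function(theta) {
    lp <- sum(vapply(seq_len(npar), function(k) priors[[k]]$logd(theta[k]), numeric(1)))
    if (!is.finite(lp)) return(-Inf)
    ll <- log_density(stats::setNames(theta, pars))
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }

  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  chains <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    theta <- if (is.null(init)) {
      vapply(priors, function(p) p$init(), numeric(1))
    } else {
      jit <- init[pars] * (1 + rnorm(npar, 0, 0.01)) + rnorm(npar, 0, 1e-3)
      pmin(pmax(jit, lo + 1e-9), hi - 1e-9)
    }
    names(theta) <- pars
    cur <- log_post(theta)
    if (!is.finite(cur)) {
      theta <- vapply(priors, function(p) p$init(), numeric(1))
      names(theta) <- pars
      cur <- log_post(theta)
    }
    if (!is.finite(cur)) abort("log density not finite at initial values")

    scale <- pmin(ifelse(is.finite(hi - lo), (hi - lo) / 10, 1), 1)
    acc <- integer(npar); tries <- integer(npar)
    draws <- matrix(NA_real_, n_keep, npar, dimnames = list(NULL, pars))
    kept <- 0L

    for (it in seq_len(config$n_iterations)) {
      for (k in seq_len(npar)) {
        prop <- theta
        prop[k] <- reflect_into(theta[k] + rnorm(1, 0, scale[k]), lo[k], hi[k])
        new <- log_post(prop)
        tries[k] <- tries[k] + 1L
        if (is.finite(new) && log(runif(1)) < new - cur) {
          theta <- prop; cur <- new; acc[k] <- acc[k] + 1L
        }
      }
      if (it <= config$n_burnin && it %% 50L == 0L) {
        rate <- acc / pmax(tries, 1L)
        scale <- scale * exp(rate - 0.44)
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > config$n_burnin && (it - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- theta
      }
    }
    chains[[ch]] <- draws[seq_len(kept), , drop = FALSE]
  }

  new_owl_posterior(chains, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_owl_posterior <- function(chains, config, model = "generic",
                              extra = list()) {
  pars <- colnames(chains[[1]])
  summ <- purrr::map_dfr(pars, function(p) {
    per_chain <- lapply(chains, function(m) m[, p])
    all_draws <- unlist(per_chain, use.names = FALSE)
    ci <- credible_interval(all_draws)
    tibble(term = p, mean = mean(all_draws),
           cri_lo = ci[1], cri_hi = ci[2],
           rhat = rhat(per_chain))
  })
  warnings <- character(0)
  bad <- summ$term[is.finite(summ$rhat) & summ$rhat >= 1.1]
  if (length(bad) > 0) {
    msg <- paste0("R-hat >= 1.1 for: ", paste(bad, collapse = ", "))
    warn(msg)
    warnings <- msg
  }
  structure(
    c(list(chains = chains, summary = summ, config = config,
           model = model, warnings = warnings), extra),
    class = c(paste0("owl_", model, "_fit"), "owl_posterior")
  )
}

#' Extract posterior draws as a tibble
#'
#' @param fit An `owl_posterior` object.
#' @return A tibble with `chain`, `iteration` and one column per parameter.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "owl_posterior"))
  purrr::map_dfr(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    bind_cols(tibble(chain = ch, iteration = seq_len(nrow(m))), as_tibble(m))
  })
}

#' @export
print.owl_posterior <- function(x, ...) {
  cat("<owl posterior: ", x$model, "> ",
      length(x$chains), " chains x ", nrow(x$chains[[1]]), " retained draws\n",
      sep = "")
  print(x$summary)
  if (length(x$warnings)) cat("warnings:", x$warnings, "\n")
  invisible(x)
}

#' Tidy posterior summaries
#'
#' `tidy()` returns one row per parameter with posterior mean, 95% credible
#' interval and R-hat; `glance()` returns one row of chain-level facts.
#'
#' @param x An `owl_posterior` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy owl_posterior
#' @export
tidy.owl_posterior <- function(x, ...) x$summary

#' @rdname tidy.owl_posterior
#' @method glance owl_posterior
#' @export
glance.owl_posterior <- function(x, ...) {
  tibble(n_chains = length(x$chains),
         n_draws = sum(vapply(x$chains, nrow, integer(1))),
         max_rhat = max(x$summary$rhat, na.rm = TRUE),
         converged = max(x$summary$rhat, na.rm = TRUE) < 1.1)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from the between- and within-chain variances.
#'
#' @param chains List of numeric vectors, one per chain (>= 2 chains of
#'   >= 10 draws each).
#' @return The R-hat estimate (>= 1 up to sampling noise; values below 1.1
#'   are taken as converged).
#' @export
#' @examples
#' set.seed(1)
#' rhat(list(rnorm(500), rnorm(500)))
rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- vapply(chains, length, integer(1))
  stopifnot(all(n >= 10))
  n <- min(n)
  chains <- lapply(chains, function(x) x[seq_len(n)])
  m <- length(chains)
  means <- vapply(chains, mean, numeric(1))
  w <- mean(vapply(chains, var, numeric(1)))
  if (w == 0) abort("zero within-chain variance")
  b <- n * var(means)
  vhat <- (n - 1) / n * w + b / n
  sqrt(vhat / w)
}

#' Equal-tailed credible interval
#'
#' @param draws Numeric vector of posterior draws (>= 100 recommended).
#' @param level Interval mass in (0, 1); default 0.95.
#' @return Length-2 numeric `c(lo, hi)` from linear-interpolation quantiles.
#' @export
#' @examples
#' credible_interval(1:1000)
credible_interval <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), names = FALSE))
}

#' Do two intervals overlap?
#'
#' Intervals are closed, so intervals touching at a point overlap. The
#' significance rule used throughout the package is *non*-overlap of 95%
#' credible intervals.
#'
#' @param a,b Length-2 numeric vectors `c(lo, hi)` with `lo <= hi`.
#' @return `TRUE` iff the intervals intersect.
#' @export
#' @examples
#' intervals_overlap(c(1, 3), c(2, 4))
#' intervals_overlap(c(1, 2), c(3, 4))
intervals_overlap <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  a[1] <= b[2] && b[1] <= a[2]
}

#' Pearson residuals
#'
#' Residual diagnostic used for all fitted models: `(y - mu)/sqrt(V(mu))`
#' with the variance function of the named family.
#'
#' @param y Observed responses.
#' @param mu Fitted means (strictly positive for `"poisson"`).
#' @param family `"poisson"`, `"gaussian"` or `"beta"`.
#' @param sd Residual standard deviation (gaussian family).
#' @param phi Beta precision (beta family; variance `mu(1-mu)/(1+phi)`).
#' @return Numeric vector of residuals.
#' @export
#' @examples
#' pearson_residuals(4, 1, "poisson")
pearson_residuals <- function(y, mu, family = c("poisson", "gaussian", "beta"),
                              sd = 1, phi = 1) {
  family <- match.arg(family)
  stopifnot(length(y) == length(mu))
  switch(family,
    poisson = {
      if (any(mu <= 0)) abort("poisson means must be positive")
      (y - mu) / sqrt(mu)
    },
    gaussian = (y - mu) / sd,
    beta = (y - mu) / sqrt(mu * (1 - mu) / (1 + phi))
  )
}
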