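#' Ground truth for synthetic studies
#'
#' Bundles every parameter the synthetic-data generators draw from, with
#' defaults set to the study's reported conditions: per-category changepoint
#' parameters of the nightly and seasonal delivery models, division-of-labor
#' coefficients, nestling-growth population parameters (changepoint near day
#' 16), adult mass trends (female seasonal decline, flat males), productivity
#' means, and the annual weather distribution (precipitation-temperature
#' correlation 0.67). Sample sizes default to the study's: 17 years, 137
#' delivery nests (~8 per observed year, 10 intervals each), 108 nestlings
#' weighed ~10 times, 174 females and 229 males, 400 productivity nests.
#'
#' @param ... Named overrides of any default element.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(...) {
  tr <- list(
    nightly = list(
      wet = c(delta1 = 48.87, beta1 = 0.04, beta2 = -0.02),
      dry = c(delta1 = 37.85, beta1 = 0.05, beta2 = -0.02),
      warm = c(delta1 = 48.50, beta1 = 0.04, beta2 = -0.02),
      cold = c(delta1 = 36.41, beta1 = 0.05, beta2 = -0.02)),
    seasonal = list(
      wet = c(delta1 = 19.10, beta1 = 0.09, beta2 = -0.08),
      dry = c(delta1 = 6.95, beta1 = 0.20, beta2 = 0.02),
      warm = c(delta1 = 19.60, beta1 = 0.09, beta2 = -0.07),
      cold = c(delta1 = 6.99, beta1 = 0.22, beta2 = 0.01)),
    x_max = c(night = 90, season = 23),
    labor = list(night = c(b0 = -1.15, b1 = 0),
                 season = c(b0 = -1.6, b1 = 0.05), phi = 10),
    unknown_frac = 0.13,
    growth = c(mu_alpha = 6, mu_b1 = 3.2, mu_b2 = -0.5, mu_delta = 16,
               sd_alpha = 0.8, sd_b1 = 0.3, sd_b2 = 0.3, sd_delta = 1.5,
               sigma_resid = 1.5),
    adult_mass = list(
      female = c(intercept = 80, slope = -0.1),
      male = c(intercept = 58, slope = 0),
      sd_intercept = 2, sd_slope = 0.02, sigma_resid = 1.5),
    productivity = c(clutch_mean = 2.7, brood_survival = 0.8,
                     fledgling_survival = 0.7, fledgling_warm_effect = 0.16),
    weather = c(precip_mean = 300.32, precip_sd = 81.67,
                temp_mean = -2.98, temp_sd = 0.48, correlation = 0.67),
    n_years = 17, nests_per_year = 8, intervals_per_nest = 10,
    n_nestlings = 108, measurements_per_nestling = 10,
    n_females = 174, n_males = 229, n_productivity_nests = 400
  )
  dots <- list(...)
  for (nm in names(dots)) tr[[nm]] <- dots[[nm]]
  structure(tr, class = "simulation_truth")
}

#' Simulate annual weather and its hourly series
#'
#' Draws correlated (precipitation, minimum-temperature) pairs from a
#' bivariate normal with the target correlation, one per owl year, then
#' expands each year into an hourly series whose [aggregate_owl_year()]
#' aggregation reproduces the drawn annual values: every day's minimum
#' hourly temperature equals the drawn annual mean (reached at 04:00, with
#' a diurnal bump above it) and the annual precipitation total is spread
#' evenly over the days at noon.
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param first_year First breeding-season calendar year.
#' @param hourly Also build the hourly expansion (skip for large `n_years`
#'   studies of the annual draws alone).
#' @return List with `years` (tibble `year_label`, `total_precip_mm`,
#'   `mean_daily_min_temp_c`) and `hourly` (weather_hourly schema, or
#'   `NULL`).
#' @export
gen_weather_years <- function(truth = simulation_truth(), seed = 1,
                              first_year = 2004, hourly = TRUE) {
  stopifnot(truth$n_years >= 2)
  set.seed(seed)
  w <- truth$weather
  rho <- w["correlation"]
  z1 <- rnorm(truth$n_years); z2 <- rnorm(truth$n_years)
  precip <- pmax(w["precip_mean"] + w["precip_sd"] * z1, 1)
  temp <- w["temp_mean"] + w["temp_sd"] * (rho * z1 + sqrt(1 - rho^2) * z2)
  years <- tibble(year_label = seq(first_year, length.out = truth$n_years),
                  total_precip_mm = unname(precip),
                  mean_daily_min_temp_c = unname(temp))
  if (!hourly) return(list(years = years, hourly = NULL))
  hourly <- purrr::map_dfr(seq_len(nrow(years)), function(i) {
    yr <- years$year_label[i]
    days <- seq(as.Date(sprintf("%d-06-01", yr - 1)),
                as.Date(sprintf("%d-05-31", yr)), by = "day")
    nd <- length(days)
    hours <- c(4L, 12L, 20L)
    tibble(timestamp = paste0(rep(as.character(days), each = length(hours)),
                              sprintf(" %02d:00:00", rep(hours, nd))),
           precip_mm = rep(c(0, years$total_precip_mm[i] / nd, 0), nd),
           temp_c = rep(c(years$mean_daily_min_temp_c[i],
                          years$mean_daily_min_temp_c[i] + 8,
                          years$mean_daily_min_temp_c[i] + 3), nd))
  })
  list(years = years, hourly = hourly)
}

#' Simulate delivery observations for one weather category
#'
#' Per-interval delivery counts are drawn as
#' `Poisson(exp(piecewise_log_rate(x)))` at the category's true changepoint
#' parameters, with `x` the interval's minutes after sunset (nightly axis)
#' or nestling age (seasonal axis). Each nest contributes
#' `intervals_per_nest` 15-min watches at ages spread over the 23-day
#' nestling period and start times in [0, 90] min after sunset. Each
#' delivery is female with the probability given by the labor model,
#' unsexed with probability `unknown_frac`, and otherwise male; per-event
#' field cues consistent with the attribution rules are attached as
#' attribute `"cues"`.
#'
#' @param truth A [simulation_truth()].
#' @param category `"wet"`, `"dry"`, `"warm"` or `"cold"`.
#' @param axis `"night"` (counts driven by time after sunset) or
#'   `"season"` (driven by nestling age).
#' @param seed Integer seed.
#' @param n_nests,intervals_per_nest Overrides of the truth's sizes.
#' @return Delivery-observation tibble (deliveries schema) with attributes
#'   `"cues"` (one row per delivery: the six cue booleans and `true_sex`)
#'   and `"true_params"`.
#' @export
gen_delivery_dataset <- function(truth = simulation_truth(), category = "dry",
                                 axis = c("night", "season"), seed = 1,
                                 n_nests = NULL, intervals_per_nest = NULL) {
  axis <- match.arg(axis)
  params <- if (axis == "night") truth$nightly[[category]] else truth$seasonal[[category]]
  if (is.null(params)) abort(paste0("no truth parameters for category ", category))
  set.seed(seed)
  n_nests <- n_nests %||% truth$nests_per_year
  ipn <- intervals_per_nest %||% truth$intervals_per_nest
  lab <- truth$labor[[axis]]
  d2 <- unname(truth$x_max[axis])

  obs <- purrr::map_dfr(seq_len(n_nests), function(n) {
    ages <- sort(sample(0:23, ipn, replace = TRUE))
    mins <- runif(ipn, 0, 90)
    tibble(nest_id = sprintf("nest%03d", n),
           obs_date = as.Date("2012-06-10") + ages,
           nest_age_days = ages,
           minutes_after_sunset = mins,
           interval_minutes = 15)
  })
  x <- if (axis == "night") obs$minutes_after_sunset else obs$nest_age_days
  rate <- exp(piecewise_log_rate(x, params["delta1"], params["beta1"],
                                 params["beta2"], 0, d2))
  total <- rpois(nrow(obs), rate)
  p_female <- plogis(lab["b0"] + lab["b1"] * x)
  n_female_all <- rbinom(nrow(obs), total, p_female)
  n_male_all <- total - n_female_all
  n_female_unk <- rbinom(nrow(obs), n_female_all, truth$unknown_frac)
  n_male_unk <- rbinom(nrow(obs), n_male_all, truth$unknown_frac)
  obs$n_male <- n_male_all - n_male_unk
  obs$n_female <- n_female_all - n_female_unk
  obs$n_unknown <- n_female_unk + n_male_unk

  cues <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    sexes <- rep(c("male", "female", "unknown"),
                 c(obs$n_male[i], obs$n_female[i], obs$n_unknown[i]))
    if (length(sexes) == 0) return(NULL)
    tibble(row = i, true_sex = sexes)
  })
  if (nrow(cues) > 0) {
    k <- sample(3, nrow(cues), replace = TRUE)
    cues$female_on_nest <- cues$true_sex == "male" & k == 1
    cues$male_vocal_delivery <- cues$true_sex == "male" & k == 2
    cues$female_vocal_off_nest <- cues$true_sex == "male" & k == 3
    cues$male_on_nest <- cues$true_sex == "female" & k == 1
    cues$female_vocal_delivery <- cues$true_sex == "female" & k == 2
    cues$male_vocal_off_nest <- cues$true_sex == "female" & k == 3
  }
  attr(obs, "cues") <- cues
  attr(obs, "true_params") <- params
  obs
}

#' Simulate nestling growth and adult mass records
#'
#' Nestlings get individual growth parameters drawn from the population
#' distribution of the hierarchical changepoint model and are weighed at
#' ages spread over the nestling period; adults are captured one to three
#' times across the season with sex-specific mass trends (declining
#' females, flat males).
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param n_nestlings,n_females,n_males Overrides of the truth's sizes.
#' @return Mass-record tibble (masses schema) with attribute
#'   `"nestling_params"` (the per-nestling truths).
#' @export
gen_growth_and_mass <- function(truth = simulation_truth(), seed = 1,
                                n_nestlings = NULL, n_females = NULL,
                                n_males = NULL) {
  set.seed(seed)
  gr <- truth$growth
  n_nestlings <- n_nestlings %||% truth$n_nestlings
  n_females <- n_females %||% truth$n_females
  n_males <- n_males %||% truth$n_males

  nl_par <- tibble(
    band_id = sprintf("N%04d", seq_len(n_nestlings)),
    alpha = rnorm(n_nestlings, gr["mu_alpha"], gr["sd_alpha"]),
    b1 = rnorm(n_nestlings, gr["mu_b1"], gr["sd_b1"]),
    b2 = rnorm(n_nestlings, gr["mu_b2"], gr["sd_b2"]),
    delta = pmin(pmax(rnorm(n_nestlings, gr["mu_delta"], gr["sd_delta"]), 2), 22))
  nestlings <- purrr::map_dfr(seq_len(n_nestlings), function(j) {
    m <- truth$measurements_per_nestling
    ages <- sort(sample(0:23, m, replace = FALSE))
    p <- nl_par[j, ]
    mu <- p$alpha + p$b1 * pmin(ages, p$delta) +
      (ages > p$delta) * p$b2 * (ages - p$delta)
    tibble(band_id = p$band_id, cohort = "nestling",
           obs_date = as.Date("2012-06-10") + ages,
           julian_day = 161L + ages, nestling_age_days = ages,
           mass_g = pmax(rnorm(m, mu, gr["sigma_resid"]), 0.5))
  })

  gen_adults <- function(n, prefix, pars) {
    am <- truth$adult_mass
    icpt <- rnorm(n, pars["intercept"], am$sd_intercept)
    slope <- rnorm(n, pars["slope"], am$sd_slope)
    purrr::map_dfr(seq_len(n), function(j) {
      k <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
      jd <- sort(sample(150:205, k))
      tibble(band_id = sprintf("%s%04d", prefix, j),
             cohort = paste0("adult_", ifelse(prefix == "F", "female", "male")),
             obs_date = as.Date("2012-01-01") + jd - 1,
             julian_day = as.integer(jd), nestling_age_days = NA_integer_,
             mass_g = rnorm(k, icpt[j] + slope[j] * jd, am$sigma_resid))
    })
  }
  out <- bind_rows(nestlings,
                   gen_adults(n_females, "F", truth$adult_mass$female),
                   gen_adults(n_males, "M", truth$adult_mass$male))
  attr(out, "nestling_params") <- nl_par
  out
}

#' Simulate nest productivity records
#'
#' Clutch sizes are Poisson truncated to 1-4 around the study's grand mean;
#' broods survive from clutches and fledglings from broods binomially, so
#' `fledglings <= brood <= clutch` always. The weather-category effect
#' multiplies the fledgling survival by `exp(effect)` in the contrast
#' category (a log-mean shift).
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param n_nests Total nests (half per category).
#' @param effect Log-scale fledgling effect of the contrast category
#'   (default the truth's warm-year value).
#' @return Tibble: nests schema plus `category_indicator` (0/1), with
#'   `fate_known = TRUE` throughout.
#' @export
gen_productivity <- function(truth = simulation_truth(), seed = 1,
                             n_nests = NULL, effect = NULL) {
  set.seed(seed)
  pr <- truth$productivity
  n_nests <- n_nests %||% truth$n_productivity_nests
  effect <- effect %||% unname(pr["fledgling_warm_effect"])
  ind <- rep(c(0L, 1L), length.out = n_nests)
  probs <- dpois(1:4, pr["clutch_mean"])
  clutch <- sample(1:4, n_nests, replace = TRUE, prob = probs / sum(probs))
  brood <- rbinom(n_nests, clutch, pr["brood_survival"])
  p_fledge <- pmin(pr["fledgling_survival"] * exp(effect * ind), 1)
  fledglings <- rbinom(n_nests, brood, p_fledge)
  tibble(nest_id = sprintf("pnest%04d", seq_len(n_nests)),
         year = 2000L + ind,
         clutch = clutch, brood = brood, fledglings = fledglings,
         fate_known = TRUE, category_indicator = ind)
}

#' Simulate a complete multi-year study
#'
#' Assembles all four pipeline inputs for one synthetic study: correlated
#' annual weather with its hourly series, delivery observations generated
#' per year at the truth of that year's wet/dry category (nightly axis),
#' productivity records with the warm-year fledgling effect, and nestling
#' plus adult mass records. Year categories are assigned the same way the
#' pipeline assigns them (ratios derived from the generated years against
#' the historical baseline), so generation and analysis agree.
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @return List with `deliveries`, `nests`, `masses`, `weather_hourly`,
#'   and the generating `years` table with its category labels.
#' @export
gen_full_study <- function(truth = simulation_truth(), seed = 1) {
  w <- gen_weather_years(truth, seed)
  bl <- derive_baseline_ratios(w$years)
  years <- classify_year(w$years, bl)

  deliveries <- purrr::map_dfr(seq_len(nrow(years)), function(i) {
    obs <- gen_delivery_dataset(truth, years$wet_dry[i], "night",
                                seed = seed + 100L + i,
                                n_nests = truth$nests_per_year)
    obs %>%
      mutate(nest_id = paste0(years$year_label[i], "_", .data$nest_id),
             obs_date = as.Date(sprintf("%d-06-10", years$year_label[i])) +
               .data$nest_age_days)
  })

  set.seed(seed + 500L)
  nests <- purrr::map_dfr(seq_len(nrow(years)), function(i) {
    n <- truth$n_productivity_nests %/% nrow(years)
    pr <- truth$productivity
    probs <- dpois(1:4, pr["clutch_mean"])
    clutch <- sample(1:4, n, replace = TRUE, prob = probs / sum(probs))
    brood <- rbinom(n, clutch, pr["brood_survival"])
    warm <- as.integer(years$warm_cold[i] == "warm")
    p_fl <- min(pr["fledgling_survival"] * exp(pr["fledgling_warm_effect"] * warm), 1)
    tibble(nest_id = sprintf("%d_pnest%03d", years$year_label[i], seq_len(n)),
           year = years$year_label[i],
           clutch = clutch, brood = brood,
           fledglings = rbinom(n, brood, p_fl),
           fate_known = TRUE)
  })

  masses <- gen_growth_and_mass(truth, seed = seed + 900L)
  list(deliveries = deliveries, nests = nests, masses = masses,
       weather_hourly = w$hourly, years = years)
}
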