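#' Chain configurations for each model family
#'
#' The reference settings per family: deliveries and productivity three
#' chains of 20,000 iterations (4,000 burn-in), growth 4,000 (2,000),
#' labor 10,000 (1,000), adult mass 200,000 (50,000). `scale` shrinks
#' iterations and burn-in proportionally for quick runs.
#'
#' @param seed Integer seed shared by all families.
#' @param scale Multiplier on iteration counts (0 < scale <= 1 typical).
#' @return Named list of [chain_config()]s.
#' @export
pipeline_configs <- function(seed = 1, scale = 1) {
  cc <- function(it, burn) {
    chain_config(3, max(round(it * scale), 200), max(round(burn * scale), 50),
                 seed = seed)
  }
  list(deliveries = cc(20000, 4000),
       growth = cc(4000, 2000),
       labor = cc(10000, 1000),
       mass = cc(200000, 50000),
       productivity = cc(20000, 4000))
}

owl_year_label <- function(dates) {
  d <- as.Date(dates)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  ifelse(m >= 6, y + 1L, y)
}

#' Run the full weather-to-provisioning analysis
#'
#' End-to-end pipeline: aggregates hourly weather into owl years, derives
#' the baseline ratios and classifies years wet/dry and warm/cold, applies
#' the observation filters and fate exclusions, then fits the requested
#' model families per weather category and assembles summary tables
#' (annual climate, rate-curve summaries, changepoint posteriors,
#' productivity effects, and the supporting labor/growth/mass models).
#'
#' @param deliveries,nests,masses,weather_hourly Input tibbles in the
#'   standard schemas (see [owlet-schemas]); read them with [read_table()].
#' @param historical_mean_precip_mm,historical_mean_min_temp_c Historical
#'   baseline means.
#' @param configs Per-family chain configs from [pipeline_configs()].
#' @param families Model families to fit, a subset of
#'   `c("deliveries", "labor", "growth", "mass", "productivity")`.
#' @param axes Predictor axes for delivery/labor models:
#'   `"night"`, `"season"` or both.
#' @param out_dir Optional directory; when given, summary tables are
#'   written as CSV plus a `summary.json` and `manifest.json`.
#' @return An `owl_pipeline` list of tibbles and fit objects; `$manifest`
#'   records the package version, seed and a config hash. Runs with the
#'   same inputs and configs produce identical summaries.
#' @export
run_pipeline <- function(deliveries, nests, masses, weather_hourly,
                         historical_mean_precip_mm = 418.1,
                         historical_mean_min_temp_c = -6.4,
                         configs = pipeline_configs(),
                         families = c("deliveries", "productivity"),
                         axes = c("night", "season"),
                         out_dir = NULL) {
  families <- match.arg(families,
                        c("deliveries", "labor", "growth", "mass", "productivity"),
                        several.ok = TRUE)
  axes <- match.arg(axes, c("night", "season"), several.ok = TRUE)

  labels <- sort(unique(owl_year_label(substr(as.character(weather_hourly$timestamp), 1, 10))))
  years <- purrr::map_dfr(labels, function(y) aggregate_owl_year(weather_hourly, y))
  bl <- derive_baseline_ratios(years, historical_mean_precip_mm,
                               historical_mean_min_temp_c)
  years <- classify_year(years, bl)

  obs <- filter_observations(deliveries)
  kept <- exclude_unknown_fate(nests, obs)
  obs <- kept$observations %>%
    mutate(year_label = owl_year_label(.data$obs_date)) %>%
    left_join(years %>% select("year_label", "wet_dry", "warm_cold"),
              by = "year_label")
  nests_cat <- kept$nests %>%
    rename(year_label = "year") %>%
    left_join(years %>% select("year_label", "wet_dry", "warm_cold"),
              by = "year_label")

  categories <- c("wet", "dry", "warm", "cold")
  cat_rows <- function(df, cat) {
    col <- if (cat %in% c("wet", "dry")) "wet_dry" else "warm_cold"
    df[!is.na(df[[col]]) & df[[col]] == cat, , drop = FALSE]
  }
  axis_col <- c(night = "minutes_after_sunset", season = "nest_age_days")

  out <- list(years = years, baseline = bl, drop_counts = attr(obs, "drop_counts"))

  if ("deliveries" %in% families) {
    fits <- list(); rates <- list(); cps <- list()
    for (ax in axes) for (cat in categories) {
      d <- cat_rows(obs, cat)
      if (nrow(d) < 10) next
      f <- fit_delivery_changepoint(d, axis_col[[ax]], configs$deliveries)
      key <- paste(ax, cat, sep = "_")
      fits[[key]] <- f
      cps[[key]] <- tidy(f) %>% mutate(axis = ax, category = cat, .before = 1)
      rates[[key]] <- rate_curve_summaries(f) %>%
        mutate(axis = ax, category = cat, .before = 1)
    }
    out$delivery_fits <- fits
    out$table_changepoints <- bind_rows(cps)
    out$table_rates <- bind_rows(rates)
  }

  if ("labor" %in% families) {
    fits <- list(); rows <- list()
    for (ax in axes) for (cat in categories) {
      d <- female_proportion(cat_rows(obs, cat), axis_col[[ax]])
      if (nrow(d) < 10) next
      f <- fit_labor_beta(d, configs$labor)
      key <- paste(ax, cat, sep = "_")
      fits[[key]] <- f
      rows[[key]] <- tidy(f) %>% mutate(axis = ax, category = cat, .before = 1)
    }
    out$labor_fits <- fits
    out$table_labor <- bind_rows(rows)
  }

  if ("growth" %in% families) {
    f <- fit_growth_hierarchical(masses, configs$growth)
    out$growth_fit <- f
    out$table_growth <- tidy(f) %>%
      filter(.data$term %in% c("mu_alpha", "mu_b1", "mu_b2", "mu_delta",
                               "sd_alpha", "sd_b1", "sd_b2", "sd_delta",
                               "sigma_resid"))
  }

  if ("mass" %in% families) {
    fits <- list(); rows <- list()
    for (sex in c("adult_female", "adult_male")) {
      f <- fit_mass_trend(masses, sex, configs$mass)
      fits[[sex]] <- f
      rows[[sex]] <- tidy(f) %>% mutate(cohort = sex, .before = 1)
    }
    out$mass_fits <- fits
    out$table_mass <- bind_rows(rows)
  }

  if ("productivity" %in% families) {
    fits <- list(); rows <- list()
    contrasts <- list(wet_dry = c(ref = "dry", alt = "wet"),
                      warm_cold = c(ref = "cold", alt = "warm"))
    for (cn in names(contrasts)) for (outc in c("clutch", "brood", "fledglings")) {
      col <- if (cn == "wet_dry") "wet_dry" else "warm_cold"
      d <- nests_cat %>%
        filter(!is.na(.data[[col]]), !is.na(.data[[outc]])) %>%
        mutate(value = .data[[outc]],
               category_indicator = as.integer(.data[[col]] == contrasts[[cn]]["alt"]))
      if (sum(d$category_indicator == 0) < 10 || sum(d$category_indicator == 1) < 10) next
      f <- fit_productivity(d %>% select("value", "category_indicator"),
                            configs$productivity)
      key <- paste(cn, outc, sep = "_")
      fits[[key]] <- f
      rows[[key]] <- tidy(f) %>% mutate(contrast = cn, outcome = outc, .before = 1)
    }
    out$productivity_fits <- fits
    out$table_productivity <- bind_rows(rows)
  }

  out$manifest <- list(
    package = "owlet",
    version = as.character(utils::packageVersion("owlet")),
    seed = configs$deliveries$seed,
    config_hash = rlang::hash(configs),
    families = families, axes = axes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$years, file.path(out_dir, "year_climate.csv"))
    for (tb in grep("^table_", names(out), value = TRUE)) {
      readr::write_csv(out[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    }
    jsonlite::write_json(
      c(out$manifest,
        list(tables = purrr::map(out[grep("^table_", names(out))], identity))),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(out) <- "owl_pipeline"
  out
}

#' @export
print.owl_pipeline <- function(x, ...) {
  cat("<owl pipeline> seed", x$manifest$seed, "\n")
  cat("years classified:", nrow(x$years), "\n")
  for (tb in grep("^table_", names(x), value = TRUE)) {
    cat("--", tb, "(", nrow(x[[tb]]), "rows )\n")
  }
  invisible(x)
}
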