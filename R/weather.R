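#' Aggregate hourly weather into an "owl year"
#'
#' All annual weather covariates run over the 12 months preceding the
#' breeding season: 1 June of the previous calendar year through 31 May of
#' the breeding year. Precipitation is the total over all hours in the
#' window; temperature is the mean over days of each day's minimum hourly
#' reading. Days with no temperature reading are skipped in the mean;
#' missing precipitation records contribute 0 with a warning.
#'
#' @param hourly Tibble in the `weather_hourly` schema; `timestamp` is
#'   POSIXct, Date, or an ISO-8601 string.
#' @param season_year Calendar year of the breeding season the owl year
#'   ends in.
#' @return One-row tibble: `year_label`, `total_precip_mm`,
#'   `mean_daily_min_temp_c`.
#' @export
aggregate_owl_year <- function(hourly, season_year) {
  d <- as.Date(substr(as.character(hourly$timestamp), 1, 10))
  lo <- as.Date(sprintf("%d-06-01", season_year - 1))
  hi <- as.Date(sprintf("%d-05-31", season_year))
  in_win <- !is.na(d) & d >= lo & d <= hi
  if (!any(in_win)) abort(sprintf("no hourly records in owl year %d (%s..%s)",
                                  season_year, lo, hi))
  p <- hourly$precip_mm[in_win]
  if (anyNA(p)) {
    warn(sprintf("%d missing precipitation record(s) treated as 0 in owl year %d",
                 sum(is.na(p)), season_year))
    p[is.na(p)] <- 0
  }
  tmp <- tibble(day = d[in_win], temp = hourly$temp_c[in_win]) %>%
    filter(!is.na(.data$temp)) %>%
    group_by(.data$day) %>%
    summarise(tmin = min(.data$temp), .groups = "drop")
  tibble(year_label = as.integer(season_year),
         total_precip_mm = sum(p),
         mean_daily_min_temp_c = mean(tmp$tmin))
}

#' Historical climate baseline
#'
#' The classification baseline: 1950-2000 means of annual (June-May)
#' precipitation and mean daily minimum temperature, plus the study-period
#' ratios that set the wet/dry and warm/cold thresholds.
#'
#' @param historical_mean_precip_mm Historical mean annual precipitation
#'   (default 418.1 mm).
#' @param historical_mean_min_temp_c Historical mean daily minimum
#'   temperature (default -6.4 deg C).
#' @param precip_ratio,temp_ratio Study-mean / historical-mean ratios
#'   (defaults 0.718 and 0.465).
#' @return A `baseline` list.
#' @export
baseline <- function(historical_mean_precip_mm = 418.1,
                     historical_mean_min_temp_c = -6.4,
                     precip_ratio = 0.718, temp_ratio = 0.465) {
  stopifnot(precip_ratio > 0, precip_ratio < 2, temp_ratio > 0, temp_ratio < 2)
  structure(list(historical_mean_precip_mm = historical_mean_precip_mm,
                 historical_mean_min_temp_c = historical_mean_min_temp_c,
                 precip_ratio = precip_ratio, temp_ratio = temp_ratio),
            class = "owl_baseline")
}

#' Derive classification ratios from study years
#'
#' The thresholds are the study-period means expressed as fractions of the
#' historical means: `precip_ratio = mean(study precip) / historical
#' precip`, and likewise for the mean daily minimum temperature (a ratio of
#' two negative Celsius quantities).
#'
#' @param study_years Tibble with `total_precip_mm` and
#'   `mean_daily_min_temp_c` columns (>= 2 rows).
#' @param historical_mean_precip_mm,historical_mean_min_temp_c Historical
#'   means.
#' @return A `baseline` object carrying the derived ratios.
#' @export
derive_baseline_ratios <- function(study_years,
                                   historical_mean_precip_mm = 418.1,
                                   historical_mean_min_temp_c = -6.4) {
  stopifnot(nrow(study_years) >= 2)
  if (historical_mean_precip_mm == 0 || historical_mean_min_temp_c == 0)
    abort("historical mean must be nonzero")
  baseline(historical_mean_precip_mm, historical_mean_min_temp_c,
           precip_ratio = mean(study_years$total_precip_mm) / historical_mean_precip_mm,
           temp_ratio = mean(study_years$mean_daily_min_temp_c) / historical_mean_min_temp_c)
}

#' Classify owl years as wet/dry and warm/cold
#'
#' A year is *wet* iff its total precipitation is strictly above
#' `precip_ratio` times the historical mean, and *warm* iff its mean daily
#' minimum temperature is strictly above `temp_ratio` times the historical
#' mean (with the default baseline, -2.976 deg C). Ties go to the
#' below-threshold category (dry/cold); none occur in practice.
#'
#' @param yc Tibble with `total_precip_mm` and `mean_daily_min_temp_c`.
#' @param bl A [baseline()].
#' @return `yc` with `wet_dry` and `warm_cold` character columns added.
#' @export
classify_year <- function(yc, bl = baseline()) {
  stopifnot(inherits(bl, "owl_baseline"))
  pt <- bl$precip_ratio * bl$historical_mean_precip_mm
  tt <- bl$temp_ratio * bl$historical_mean_min_temp_c
  yc %>%
    mutate(wet_dry = ifelse(.data$total_precip_mm > pt, "wet", "dry"),
           warm_cold = ifelse(.data$mean_daily_min_temp_c > tt, "warm", "cold"))
}

#' Pearson correlation screen for annual covariates
#'
#' Annual precipitation and temperature are screened for collinearity
#' before being used as separate predictors.
#'
#' @param precip,temp Equal-length numeric vectors (n >= 3).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
correlation_screen <- function(precip, temp) {
  stopifnot(length(precip) == length(temp), length(precip) >= 3)
  if (sd(precip) == 0 || sd(temp) == 0) abort("zero variance in input")
  ct <- cor.test(precip, temp, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(precip))
}

#' Rank candidate covariate windows by AIC
#'
#' For each candidate annual covariate (a column of `data`), fits a
#' log-link Poisson regression of per-interval delivery counts on that
#' scalar covariate by maximum likelihood and ranks the candidates by AIC.
#' The winner (lowest AIC) is the covariate carried into subsequent
#' analyses. Non-convergence of a fit is flagged per window, not fatal.
#'
#' @param data Tibble with one row per delivery interval, a count column,
#'   and one column per candidate covariate.
#' @param candidates Character vector of candidate column names.
#' @param count_col Name of the count column (default `"count"`).
#' @return Tibble sorted by ascending AIC: `window`, `aic`, `delta_aic`,
#'   `converged`.
#' @export
select_window_aic <- function(data, candidates, count_col = "count") {
  stopifnot(length(candidates) >= 1, all(candidates %in% names(data)),
            count_col %in% names(data))
  y <- data[[count_col]]
  stopifnot(all(y >= 0))
  res <- purrr::map_dfr(candidates, function(cand) {
    fit <- tryCatch(glm(y ~ x, family = poisson(),
                        data = tibble(y = y, x = data[[cand]])),
                    error = function(e) NULL)
    if (is.null(fit)) {
      tibble(window = cand, aic = NA_real_, converged = FALSE)
    } else {
      tibble(window = cand, aic = AIC(fit), converged = fit$converged)
    }
  })
  res %>%
    arrange(.data$aic) %>%
    mutate(delta_aic = .data$aic - min(.data$aic, na.rm = TRUE))
}
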