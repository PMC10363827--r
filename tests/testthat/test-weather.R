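make_hourly <- function(days, temps_by_hour, precip = 0) {
  purrr::map_dfr(as.character(days), function(d) {
    tibble::tibble(timestamp = paste0(d, sprintf(" %02d:00:00", seq_along(temps_by_hour) - 1)),
                   precip_mm = precip, temp_c = temps_by_hour)
  })
}

test_that("owl-year aggregation totals precipitation and averages daily minima", {
  days <- seq(as.Date("2011-06-01"), as.Date("2012-05-31"), by = "day")
  hourly <- make_hourly(days, c(-5, -5, -5))
  agg <- aggregate_owl_year(hourly, 2012)
  expect_equal(agg$mean_daily_min_temp_c, -5)
  expect_equal(agg$total_precip_mm, 0)

  one_rain <- hourly
  one_rain$precip_mm[100] <- 3
  expect_equal(aggregate_owl_year(one_rain, 2012)$total_precip_mm, 3)

  # records outside the June-May window are ignored
  outside <- dplyr::bind_rows(hourly,
    tibble::tibble(timestamp = "2012-06-01 00:00:00", precip_mm = 99, temp_c = 10))
  expect_equal(aggregate_owl_year(outside, 2012)$total_precip_mm, 0)

  expect_error(aggregate_owl_year(hourly, 1990), "no hourly records")
})

test_that("a year scripted to the 2004 totals reproduces them and classifies dry/cold", {
  days <- seq(as.Date("2003-06-01"), as.Date("2004-05-31"), by = "day")
  nd <- length(days)
  hourly <- make_hourly(days, c(-3.07, 0, 2), precip = 0)
  hourly$precip_mm[hourly$timestamp == paste0(days[50], " 01:00:00")] <- 224.03
  agg <- aggregate_owl_year(hourly, 2004)
  expect_equal(agg$total_precip_mm, 224.03)
  expect_equal(agg$mean_daily_min_temp_c, -3.07)
  cl <- classify_year(agg, baseline())
  expect_equal(cl$wet_dry, "dry")
  expect_equal(cl$warm_cold, "cold")
})

test_that("classification is invariant to permuting readings within a day", {
  days <- seq(as.Date("2011-06-01"), as.Date("2012-05-31"), by = "day")
  set.seed(7)
  hourly <- make_hourly(days, c(-4, -1, 3), precip = 0.05)
  shuffled <- hourly[sample(nrow(hourly)), ]
  expect_equal(aggregate_owl_year(shuffled, 2012),
               aggregate_owl_year(hourly, 2012))
})

test_that("ties at the classification threshold go below (dry/cold)", {
  bl <- baseline(historical_mean_precip_mm = 400, historical_mean_min_temp_c = -6,
                 precip_ratio = 0.75, temp_ratio = 0.5)
  yc <- tibble::tibble(total_precip_mm = 300, mean_daily_min_temp_c = -3)
  cl <- classify_year(yc, bl)
  expect_equal(cl$wet_dry, "dry")
  expect_equal(cl$warm_cold, "cold")
})

test_that("baseline ratios derive from study-period means", {
  t1 <- table1_fixture()
  bl <- derive_baseline_ratios(t1)
  expect_equal(bl$precip_ratio, 0.718, tolerance = 0.001)
  expect_equal(bl$temp_ratio, 0.466, tolerance = 0.001)
  same <- tibble::tibble(total_precip_mm = c(418.1, 418.1),
                         mean_daily_min_temp_c = c(-6.4, -6.4))
  expect_equal(derive_baseline_ratios(same)$precip_ratio, 1)
  expect_equal(derive_baseline_ratios(same)$temp_ratio, 1)
})

test_that("correlation screen matches cor.test and rejects degenerate input", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlation_screen(x, x)$r, 1)
  expect_equal(correlation_screen(x, -x)$r, -1)
  expect_error(correlation_screen(x, rep(1, 5)), "variance")
})

test_that("AIC window selection picks the generating covariate", {
  set.seed(11)
  n <- 200
  a <- rnorm(n)
  b <- rnorm(n)
  counts <- rpois(n, exp(0.8 + 0.5 * a))
  d <- tibble::tibble(count = counts, a = a, b = b)
  rk <- select_window_aic(d, c("a", "b"))
  expect_equal(rk$window[1], "a")
  expect_lt(rk$aic[1], rk$aic[2])
  expect_equal(rk$delta_aic[1], 0)

  # single candidate trivially wins
  expect_equal(select_window_aic(d, "b")$window, "b")

  # duplicated covariate gives equal AIC
  d$a2 <- d$a
  rk2 <- select_window_aic(d, c("a", "a2"))
  expect_lt(abs(rk2$aic[1] - rk2$aic[2]), 1e-6)

  # affine rescaling does not change the ranking (log link with intercept)
  d$a_scaled <- 100 * d$a + 7
  rk3 <- select_window_aic(d, c("a_scaled", "b"))
  expect_equal(rk3$window[1], "a_scaled")
  expect_equal(rk3$aic[rk3$window == "a_scaled"], rk$aic[rk$window == "a"],
               tolerance = 1e-8)
})
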