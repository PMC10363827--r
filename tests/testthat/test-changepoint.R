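test_that("the piecewise log-rate is zero at the origin and continuous", {
  expect_equal(piecewise_log_rate(0, 40, 0.05, -0.02, 0, 90), 0)
  # hand evaluation at the dry-year nightly posterior means
  expect_equal(piecewise_log_rate(60, 37.85, 0.05, -0.02, 0, 90),
               0.05 * 37.85 - 0.02 * 22.15)
  # continuity: approaching the changepoint from both segments
  d1 <- 37.85
  left <- piecewise_log_rate(d1, d1, 0.05, -0.02, 0, 90)
  right <- piecewise_log_rate(d1 + 1e-9, d1, 0.05, -0.02, 0, 90)
  expect_equal(left, right, tolerance = 1e-7)
  expect_equal(left, 0.05 * d1)
  expect_error(piecewise_log_rate(95, 40, 0.05, -0.02, 0, 90), "outside")
})

test_that("the delivery fit recovers simulated changepoint parameters", {
  truth <- simulation_truth()$nightly$dry
  obs <- gen_delivery_dataset(simulation_truth(), "dry", "night", seed = 21,
                              n_nests = 60, intervals_per_nest = 10)
  fit <- fit_delivery_changepoint(obs, "minutes_after_sunset",
                                  quick_config(seed = 6))
  s <- tidy(fit)
  for (p in c("delta1", "beta1", "beta2")) {
    row <- s[s$term == p, ]
    expect_lt(row$cri_lo, truth[[p]])
    expect_gt(row$cri_hi, truth[[p]])
  }
  expect_true(all(s$rhat < 1.1))

  # structural identities on every retained draw
  draws <- do.call(rbind, fit$chains)
  at0 <- exp(apply(draws, 1, function(d)
    piecewise_log_rate(0, d["delta1"], d["beta1"], d["beta2"], 0, fit$delta2)))
  expect_true(all(at0 == 1))
  gap <- apply(draws, 1, function(d) {
    piecewise_log_rate(d["delta1"], d["delta1"], d["beta1"], d["beta2"], 0, fit$delta2) -
      (d["beta1"] * d["delta1"])
  })
  expect_lt(max(abs(gap)), 1e-12)
})

test_that("null data leave both slopes consistent with zero", {
  obs <- tibble::tibble(nest_id = "n", obs_date = as.Date("2012-06-10"),
                        nest_age_days = 5,
                        minutes_after_sunset = rep(seq(5, 85, by = 5), each = 4),
                        interval_minutes = 15,
                        n_male = 1, n_female = 0, n_unknown = 0)
  fit <- fit_delivery_changepoint(obs, "minutes_after_sunset",
                                  quick_config(seed = 2))
  s <- tidy(fit)
  for (p in c("beta1", "beta2")) {
    row <- s[s$term == p, ]
    expect_lt(row$cri_lo, 0)
    expect_gt(row$cri_hi, 0)
  }
})

test_that("rate-curve functionals summarise scripted draws correctly", {
  x <- seq(0, 10, by = 1)
  # zero slopes: flat curve at exp(0) = 1
  flat <- manual_delivery_fit(
    cbind(delta1 = rep(5, 200), beta1 = 0, beta2 = 0), delta2 = 10, x = x)
  s <- rate_curve_summaries(flat)
  expect_equal(s$estimate, c(1, 1, 1))
  expect_equal(s$cri_lo, s$cri_hi)

  # monotone single segment: maximum at the end of the grid
  mono <- manual_delivery_fit(
    cbind(delta1 = rep(10, 200), beta1 = 0.1, beta2 = 0), delta2 = 10, x = x)
  s2 <- rate_curve_summaries(mono)
  expect_equal(s2$estimate[s2$functional == "max"], exp(1))
  expect_equal(s2$estimate[s2$functional == "min"], 1)
  expect_error(rate_curve_summaries(mono, numeric(0)), "empty")
})

test_that("the profile-likelihood oracle honours its grid and tie-breaks", {
  set.seed(13)
  x <- runif(400, 0, 90)
  y <- rpois(400, exp(piecewise_log_rate(x, 40, 0.05, -0.02, 0, 90)))
  one <- changepoint_profile_oracle(x, y, grid = 33)
  expect_equal(one$delta1, 33)

  # no changepoint in truth (beta2 continues beta1): profile flat in delta1,
  # documented tie-break to the smallest grid value
  y2 <- rpois(400, exp(0.02 * x))
  flat_fit <- glm(y2 ~ 0 + x, family = poisson())
  prof <- changepoint_profile_oracle(x, y2, grid = c(30, 45, 60))
  expect_lt(abs(prof$log_lik - as.numeric(logLik(flat_fit))), 2.5)

  # exact ties (duplicated grid point) resolve to the earliest grid entry
  tie <- changepoint_profile_oracle(x, y, grid = c(40, 40))
  expect_equal(tie$delta1, 40)
  expect_equal(nrow(tie$profile), 2)
})
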