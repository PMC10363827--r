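test_that("generators are deterministic under a fixed seed", {
  tr <- simulation_truth(n_years = 4, nests_per_year = 3)
  expect_identical(gen_weather_years(tr, seed = 2), gen_weather_years(tr, seed = 2))
  expect_identical(gen_delivery_dataset(tr, "dry", "night", seed = 2),
                   gen_delivery_dataset(tr, "dry", "night", seed = 2))
  expect_identical(gen_productivity(tr, seed = 2, n_nests = 50),
                   gen_productivity(tr, seed = 2, n_nests = 50))
  expect_false(identical(gen_delivery_dataset(tr, "dry", "night", seed = 2),
                         gen_delivery_dataset(tr, "dry", "night", seed = 3)))
})

test_that("hourly expansion round-trips through owl-year aggregation", {
  tr <- simulation_truth(n_years = 3)
  w <- gen_weather_years(tr, seed = 12)
  for (i in seq_len(3)) {
    agg <- aggregate_owl_year(w$hourly, w$years$year_label[i])
    expect_equal(agg$total_precip_mm, w$years$total_precip_mm[i], tolerance = 1e-9)
    expect_equal(agg$mean_daily_min_temp_c, w$years$mean_daily_min_temp_c[i],
                 tolerance = 1e-12)
  }
})

test_that("annual draws hit the target precipitation-temperature correlation", {
  tr <- simulation_truth(n_years = 10000)
  w <- gen_weather_years(tr, seed = 14, hourly = FALSE)
  r <- cor(w$years$total_precip_mm, w$years$mean_daily_min_temp_c)
  expect_equal(r, 0.67, tolerance = 0.02)
  w0 <- gen_weather_years(simulation_truth(
    n_years = 10000, weather = c(precip_mean = 300, precip_sd = 80,
                                 temp_mean = -3, temp_sd = 0.5, correlation = 0)),
    seed = 15, hourly = FALSE)
  expect_lt(abs(cor(w0$years$total_precip_mm, w0$years$mean_daily_min_temp_c)),
            0.03)
})

test_that("delivery counts follow the scripted intensity and cue bookkeeping", {
  tr <- simulation_truth()
  obs <- gen_delivery_dataset(tr, "dry", "night", seed = 22, n_nests = 300)
  p <- tr$nightly$dry
  expected <- exp(piecewise_log_rate(obs$minutes_after_sunset,
                                     p["delta1"], p["beta1"], p["beta2"], 0, 90))
  total <- obs$n_male + obs$n_female + obs$n_unknown
  expect_equal(mean(total), mean(expected), tolerance = 0.03)
  expect_true(all(total >= 0))
  # near the origin the expected count approaches exp(0) = 1
  lowx <- obs$minutes_after_sunset < 5
  expect_equal(mean(total[lowx]), 1, tolerance = 0.15)

  # attribution cues replay to exactly the generated per-sex counts
  cues <- attr(obs, "cues")
  replayed <- attribute_sex(cues$female_on_nest, cues$male_vocal_delivery,
                            cues$female_vocal_off_nest, cues$male_on_nest,
                            cues$female_vocal_delivery, cues$male_vocal_off_nest)
  expect_equal(replayed, cues$true_sex)
  agg <- table(factor(replayed, c("male", "female", "unknown")))
  expect_equal(unname(agg[["male"]]), sum(obs$n_male))
  expect_equal(unname(agg[["female"]]), sum(obs$n_female))
  expect_equal(unname(agg[["unknown"]]), sum(obs$n_unknown))

  # zero unknown fraction: no unsexed deliveries
  none <- gen_delivery_dataset(simulation_truth(unknown_frac = 0), "dry",
                               "night", seed = 23, n_nests = 40)
  expect_true(all(none$n_unknown == 0))

  # filtering the generator's output is the identity (all intervals valid)
  kept <- filter_observations(obs)
  expect_equal(nrow(kept), nrow(obs))
})

test_that("growth records respect the hierarchical truth", {
  tr <- simulation_truth(growth = c(mu_alpha = 6, mu_b1 = 3.2, mu_b2 = -0.5,
                                    mu_delta = 16, sd_alpha = 0, sd_b1 = 0,
                                    sd_b2 = 0, sd_delta = 0, sigma_resid = 1e-9))
  m <- gen_growth_and_mass(tr, seed = 33, n_nestlings = 6, n_females = 2,
                           n_males = 2)
  nl <- m[m$cohort == "nestling", ]
  mu <- 6 + 3.2 * pmin(nl$nestling_age_days, 16) +
    (nl$nestling_age_days > 16) * (-0.5) * (nl$nestling_age_days - 16)
  expect_equal(nl$mass_g, mu, tolerance = 1e-6)
  expect_true(all(is.na(m$nestling_age_days[m$cohort != "nestling"])))
  expect_true(all(m$mass_g > 0))
})

test_that("productivity counts respect the stage ordering", {
  tr <- simulation_truth()
  pr <- gen_productivity(tr, seed = 44, n_nests = 2000)
  expect_true(all(pr$fledglings <= pr$brood))
  expect_true(all(pr$brood <= pr$clutch))
  expect_true(all(pr$clutch >= 1 & pr$clutch <= 4))
  expect_equal(mean(pr$clutch), 2.7, tolerance = 0.15)

  # perfect survival collapses the three stages
  sure <- simulation_truth(productivity = c(clutch_mean = 2.7, brood_survival = 1,
                                            fledgling_survival = 1,
                                            fledgling_warm_effect = 0))
  pr1 <- gen_productivity(sure, seed = 45, n_nests = 200)
  expect_equal(pr1$clutch, pr1$brood)
  expect_equal(pr1$brood, pr1$fledglings)
})
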