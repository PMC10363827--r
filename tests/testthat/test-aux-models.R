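test_that("female proportions exclude unsexed deliveries and squeeze the bounds", {
  obs <- tibble::tibble(nest_id = c("a", "b", "c"),
                        minutes_after_sunset = c(10, 20, 30),
                        nest_age_days = c(3, 9, 15),
                        n_male = c(3, 0, 0), n_female = c(1, 0, 96),
                        n_unknown = c(5, 2, 0))
  lp <- female_proportion(obs)
  # interval with no sexed delivery is dropped
  expect_equal(lp$nest_id, c("a", "c"))
  # dataset N = 100 sexed deliveries; p = 0.25 squeezes to (0.25*99+0.5)/100
  expect_equal(lp$p_female[1], (0.25 * 99 + 0.5) / 100)
  # boundary p = 1 pulled strictly inside
  expect_lt(lp$p_female[2], 1)
  expect_equal(lp$p_female[2], (1 * 99 + 0.5) / 100)

  # squeeze of p = 0 with N = 100
  zero <- tibble::tibble(nest_id = "z", minutes_after_sunset = 1, nest_age_days = 1,
                         n_male = 100, n_female = 0, n_unknown = 0)
  expect_equal(female_proportion(zero)$p_female, 0.005)

  # squeeze is monotone and bounded away from the boundaries
  n <- 50
  p <- seq(0, 1, length.out = 11)
  sq <- (p * (n - 1) + 0.5) / n
  expect_true(all(diff(sq) > 0))
  expect_true(all(sq > 0 & sq < 1))
})

test_that("the labor beta GLM detects an age trend and respects null data", {
  obs <- gen_delivery_dataset(simulation_truth(), "dry", "season", seed = 41,
                              n_nests = 50)
  lp <- female_proportion(obs, "nest_age_days")
  fit <- fit_labor_beta(lp, chain_config(3, 4000, 800, seed = 6))
  s <- tidy(fit)
  b1 <- s[s$term == "b1", ]
  expect_gt(b1$cri_lo, 0)               # female share rises with nestling age
  expect_lt(abs(b1$mean - 0.05), 0.03)
  expect_true(all(s$rhat < 1.1))
  # fitted means stay inside (0, 1)
  draws <- posterior_draws(fit)
  mus <- plogis(draws$b0 + draws$b1 * max(lp$x))
  expect_true(all(mus > 0 & mus < 1))

  # flat response at 0.5: no trend
  flat <- tibble::tibble(nest_id = "n", x = rep(seq(0, 23, by = 1), 3),
                         p_female = 0.5, n_sexed = 4)
  fit0 <- fit_labor_beta(flat, chain_config(3, 3000, 600, seed = 2))
  b10 <- tidy(fit0)[tidy(fit0)$term == "b1", ]
  expect_lt(b10$cri_lo, 0)
  expect_gt(b10$cri_hi, 0)
})

test_that("adult mass trends are recovered per sex", {
  m <- gen_growth_and_mass(simulation_truth(), seed = 51,
                           n_nestlings = 5, n_females = 60, n_males = 60)
  ff <- fit_mass_trend(m, "adult_female", chain_config(3, 6000, 2500, seed = 7))
  sf <- tidy(ff)
  slope_f <- sf[sf$term == "slope", ]
  expect_lt(slope_f$cri_hi, 0)          # significant female decline
  expect_lt(slope_f$cri_lo, -0.1)
  expect_gt(slope_f$cri_hi, -0.1)       # and the CRI covers the truth

  fm <- fit_mass_trend(m, "adult_male", chain_config(3, 6000, 2500, seed = 7))
  slope_m <- tidy(fm)[tidy(fm)$term == "slope", ]
  expect_lt(slope_m$cri_lo, 0)
  expect_gt(slope_m$cri_hi, 0)          # no male trend

  # intercept reporting scale: centred vs raw differ by slope * mean(julian)
  fc <- fit_mass_trend(m, "adult_female", chain_config(2, 1500, 500, seed = 7),
                       centre = TRUE)
  sc <- tidy(fc)
  expect_gt(abs(sc$mean[sc$term == "intercept"] -
                sf$mean[sf$term == "intercept"]), 1)
})

test_that("five birds on one exact line pin the fixed slope to it", {
  jd <- c(150, 200)
  d <- purrr::map_dfr(1:5, function(j) {
    tibble::tibble(band_id = paste0("F", j), cohort = "adult_female",
                   obs_date = as.Date("2012-01-01") + jd, julian_day = jd,
                   nestling_age_days = NA_integer_,
                   mass_g = 80 - 0.1 * jd + rnorm(2, 0, 0.01))
  })
  fit <- fit_mass_trend(d, "adult_female", chain_config(3, 3000, 1500, seed = 3))
  s <- tidy(fit)
  expect_equal(s$mean[s$term == "slope"], -0.1, tolerance = 0.01)
})

test_that("the productivity GLM measures category effects on counts", {
  tr <- simulation_truth()
  pr <- gen_productivity(tr, seed = 61, n_nests = 2000)
  d <- dplyr::mutate(pr, value = fledglings)[, c("value", "category_indicator")]
  fit <- fit_productivity(d, chain_config(3, 4000, 800, seed = 5))
  s <- tidy(fit)
  c1 <- s[s$term == "c1", ]
  expect_lt(c1$cri_lo, 0.16)
  expect_gt(c1$cri_hi, 0.16)            # CRI covers the simulated effect
  # posterior category means are positive and ordered with the effect
  expect_gt(s$mean[s$term == "mean_alt"], s$mean[s$term == "mean_ref"])
  expect_true(all(s$mean[s$term %in% c("mean_ref", "mean_alt")] > 0))
  # conjugate-limit sanity: posterior mean of exp(c0) ~ sample mean
  expect_equal(s$mean[s$term == "mean_ref"],
               mean(d$value[d$category_indicator == 0]), tolerance = 0.02)

  # identical category means: effect consistent with zero
  null <- gen_productivity(tr, seed = 62, n_nests = 600, effect = 0)
  dn <- dplyr::mutate(null, value = fledglings)[, c("value", "category_indicator")]
  s0 <- tidy(fit_productivity(dn, chain_config(3, 3000, 600, seed = 5)))
  expect_lt(s0$cri_lo[s0$term == "c1"], 0)
  expect_gt(s0$cri_hi[s0$term == "c1"], 0)

  # degenerate: a category of all zeros still yields a finite posterior
  dz <- tibble::tibble(value = c(rpois(15, 2), rep(0, 15)),
                       category_indicator = rep(c(0, 1), each = 15))
  expect_message(fz <- fit_productivity(dz, chain_config(2, 1500, 400, seed = 2)),
                 "prior-dominated")
  expect_true(all(is.finite(tidy(fz)$mean)))
})
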