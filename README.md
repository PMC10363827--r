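# owlet

Year-round weather and nest provisioning in Flammulated Owls
(*Psiloscops flammeolus*) — a tidyverse-native R implementation of the
full analysis pipeline, for ecologists studying how annual precipitation
and temperature shape breeding behaviour in a single-prey-loading
insectivore.

Because the species carries exactly one prey item per nest visit, visit
counts per 15-min watch are prey counts. The package:

* aggregates hourly weather into June–May "owl years" and classifies each
  as **wet/dry** and **warm/cold** against a 1950–2000 baseline
  (418.1 mm; −6.4 °C), with AIC screening of candidate covariate windows
  and a Pearson collinearity screen;
* fits the core model — a **Bayesian two-segment changepoint Poisson
  regression** of per-interval delivery counts, joined at the changepoint
  with a zero intercept and log link,

  $$\log\gamma(x) = \beta_1(\min(x,\Delta_1)-\Delta_0) +
    \mathbf{1}[x>\Delta_1]\,\beta_2(\min(x,\Delta_2)-\Delta_1),$$

  so the expected count at the origin is exactly $e^0 = 1$ — separately
  per weather category, nightly (minutes after sunset) and seasonally
  (nestling age);
* fits the supporting models: a hierarchical Gaussian growth model with a
  per-nestling changepoint near day 16, a beta GLM of the female share of
  deliveries, adult-mass mixed models on Julian day, and productivity
  Poisson GLMs, all judged by the overlap of 95% credible intervals;
* samples every posterior with an in-package adaptive random-walk
  Metropolis sampler (deterministic per seed, Gelman–Rubin diagnostics),
  cross-checked against a profile-likelihood changepoint oracle built on
  `glm()`;
* generates complete **synthetic studies with known ground truth**
  (`simulation_truth()`, `gen_*()`), so every stage is testable without
  the field data.

All user-facing functions take a data frame first and return tibbles;
fitted models have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate nightly delivery watches at the dry-year truth (changepoint
37.85 min after sunset, rising slope 0.05, falling slope −0.02), fit the
changepoint model, and summarise:

```r
library(owlet)

obs <- gen_delivery_dataset(simulation_truth(), category = "dry",
                            axis = "night", seed = 11,
                            n_nests = 80, intervals_per_nest = 10)
fit <- fit_delivery_changepoint(obs, "minutes_after_sunset",
                                chain_config(3, 4000, 1000, seed = 5))
tidy(fit)
#> # A tibble: 3 x 5
#>   term      mean  cri_lo  cri_hi  rhat
#>   <chr>    <dbl>   <dbl>   <dbl> <dbl>
#> 1 delta1 38.3    36.7    40.0     1.01
#> 2 beta1   0.0500  0.0475  0.0523  1.00
#> 3 beta2  -0.0208 -0.0239 -0.0179  1.00

rate_curve_summaries(fit)
#> # A tibble: 3 x 4
#>   functional estimate cri_lo cri_hi
#>   <chr>         <dbl>  <dbl>  <dbl>
#> 1 mean           3.67   3.55   3.81
#> 2 min            1.01   1.01   1.01
#> 3 max            6.78   6.39   7.19

autoplot(fit)   # observed counts, posterior-mean curve, 95% CRI ribbon
```

The posterior means sit on the generating truth; the 95% CRIs cover all
three parameters; the delivery rate peaks near 6.8 prey per 15 min at the
changepoint and the minimum expected rate is ~1 (the zero-intercept
identity). The classification stage reproduces the published 17-year
record exactly:

```r
t1 <- table1_fixture()
bl <- derive_baseline_ratios(t1)       # 71.8% precip, 46.5% temperature
cl <- classify_year(t1, bl)
all(cl$wet_dry == t1$wet_dry)          # TRUE (17/17)
```

An end-to-end run over all stages is `run_pipeline()`; see
`vignette("weather-provisioning-methods")` for the models, priors, and
design choices.

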