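# Shared helpers: tiny CSV fixtures written at test time and short chain
# configs sized so the whole suite runs in minutes.

write_deliveries_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- "nest_id,obs_date,nest_age_days,minutes_after_sunset,interval_minutes,n_male,n_female,n_unknown"
  writeLines(c(header, lines), path)
  path
}

quick_config <- function(iters = 3000, burn = 1000, seed = 1) {
  chain_config(3, iters, burn, seed = seed)
}

# manual delivery-fit object with scripted draws, for summary-functional tests
manual_delivery_fit <- function(draws, delta2, x) {
  structure(list(chains = list(draws), delta0 = 0, delta2 = delta2,
                 data = tibble::tibble(x = x, y = rep(1, length(x))),
                 x_axis = "minutes_after_sunset"),
            class = c("owl_delivery_fit", "owl_posterior"))
}
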