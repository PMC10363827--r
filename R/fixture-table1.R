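#' Published yearly climate and productivity summary
#'
#' The 17-year summary table of annual (June-May) climate and nest
#' productivity from the Colorado Flammulated Owl study: total
#' precipitation, mean daily minimum temperature, the published wet/dry
#' and warm/cold labels, nest counts for the prey-delivery and
#' productivity/mass datasets, and per-year mean clutch, brood and
#' fledgling counts. Packaged verbatim as a classification and accounting
#' fixture; no prey-delivery observations were made in 2008, 2010 or 2016.
#'
#' @return A 17-row tibble with columns `year`, `total_precip_mm`,
#'   `mean_daily_min_temp_c`, `wet_dry`, `warm_cold`, `nests_delivery`,
#'   `nests_productivity`, `mean_clutch`, `mean_brood`, `mean_fledglings`.
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  tibble::tribble(
    ~year, ~total_precip_mm, ~mean_daily_min_temp_c, ~wet_dry, ~warm_cold,
    ~nests_delivery, ~nests_productivity, ~mean_clutch, ~mean_brood, ~mean_fledglings,
    2004L, 224.03, -3.07, "dry", "cold", 11L, 21L, 3.00, 2.74, 2.45,
    2005L, 326.64, -2.63, "wet", "warm", 11L, 27L, 2.75, 1.81, 1.74,
    2006L, 180.34, -3.30, "dry", "cold",  4L, 22L, 2.78, 1.90, 0.55,
    2007L, 455.68, -2.91, "wet", "warm",  7L, 24L, 2.40, 1.74, 1.29,
    2008L, 286.77, -3.36, "dry", "cold",  0L, 22L, 2.38, 1.48, 1.23,
    2009L, 276.61, -2.99, "dry", "cold",  9L, 23L, 2.72, 1.48, 1.17,
    2010L, 333.25, -3.95, "wet", "cold",  0L, 24L, 2.59, 2.05, 1.42,
    2011L, 340.11, -2.93, "wet", "warm",  9L, 20L, 2.68, 1.89, 1.25,
    2012L, 308.61, -2.68, "wet", "warm",  9L, 26L, 2.69, 2.05, 1.19,
    2013L, 236.73, -3.65, "dry", "cold", 15L, 28L, 2.65, 2.04, 1.75,
    2014L, 279.15, -2.88, "dry", "warm", 15L, 37L, 2.67, 2.28, 2.05,
    2015L, 506.98, -2.32, "wet", "warm",  8L, 23L, 2.55, 1.87, 1.70,
    2016L, 303.02, -2.54, "wet", "warm",  0L, 18L, 2.90, 2.59, 2.33,
    2017L, 291.08, -2.18, "dry", "warm",  7L, 27L, 2.83, 2.33, 2.15,
    2018L, 302.77, -2.58, "wet", "warm", 10L, 19L, 2.61, 2.21, 2.00,
    2019L, 219.71, -3.48, "dry", "cold",  9L, 25L, 2.61, 1.80, 1.60,
    2020L, 233.93, -3.25, "dry", "cold", 13L, 14L, 3.08, 2.62, 2.07
  )
}
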