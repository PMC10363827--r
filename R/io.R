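#' CSV schemas
#'
#' The pipeline reads and writes four comma-separated, UTF-8, one-header-row
#' tables (ISO-8601 dates, `.` decimal):
#'
#' * `deliveries`: `nest_id, obs_date, nest_age_days, minutes_after_sunset,
#'   interval_minutes, n_male, n_female, n_unknown` — one 15-min nest watch
#'   with per-sex prey-delivery counts.
#' * `nests`: `nest_id, year, clutch, brood, fledglings, fate_known` — one
#'   productivity record per nest (counts may be missing stage-wise).
#' * `masses`: `band_id, cohort, obs_date, julian_day, nestling_age_days,
#'   mass_g` — one capture; `cohort` is `adult_male`, `adult_female` or
#'   `nestling` (only nestlings carry `nestling_age_days`).
#' * `weather_hourly`: `timestamp, precip_mm, temp_c`.
#'
#' @name owlet-schemas
NULL

owlet_schemas <- list(
  deliveries = list(
    required = c("nest_id", "obs_date", "nest_age_days", "minutes_after_sunset",
                 "interval_minutes", "n_male", "n_female", "n_unknown"),
    numeric = c("nest_age_days", "minutes_after_sunset", "interval_minutes",
                "n_male", "n_female", "n_unknown"),
    date = "obs_date"
  ),
  nests = list(
    required = c("nest_id", "year", "clutch", "brood", "fledglings", "fate_known"),
    numeric = c("clutch", "brood", "fledglings"),
    logical = "fate_known",
    allow_na = c("clutch", "brood", "fledglings")
  ),
  masses = list(
    required = c("band_id", "cohort", "obs_date", "julian_day",
                 "nestling_age_days", "mass_g"),
    numeric = c("julian_day", "nestling_age_days", "mass_g"),
    date = "obs_date",
    allow_na = "nestling_age_days"
  ),
  weather_hourly = list(
    required = c("timestamp", "precip_mm", "temp_c"),
    numeric = c("precip_mm", "temp_c"),
    allow_na = c("precip_mm", "temp_c")
  )
)

#' Read a pipeline table
#'
#' Reads one of the four standard CSVs (see [owlet-schemas]) with per-row
#' validation: a missing required column is an error naming the column;
#' a row whose required field fails to parse is dropped with a row-indexed
#' message while the remaining rows load.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"deliveries"`, `"nests"`, `"masses"`,
#'   `"weather_hourly"`.
#' @return A tibble of typed records. Rejected row indices (in file order)
#'   are attached as attribute `"rejected_rows"`.
#' @export
read_table <- function(path, schema = names(owlet_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  sc <- owlet_schemas[[schema]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(sc$required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s) in ", schema, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw
  bad <- rep(FALSE, nrow(raw))
  allow_na <- sc$allow_na %||% character(0)
  for (col in sc$numeric %||% character(0)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    fail <- is.na(v) & !is.na(raw[[col]])
    if (!col %in% allow_na) fail <- fail | is.na(raw[[col]])
    bad <- bad | fail
    out[[col]] <- v
  }
  for (col in sc$date %||% character(0)) {
    v <- as.Date(raw[[col]], format = "%Y-%m-%d")
    bad <- bad | is.na(v)
    out[[col]] <- v
  }
  for (col in sc$logical %||% character(0)) {
    v <- toupper(trimws(raw[[col]])) %in% c("TRUE", "T", "1")
    v[is.na(raw[[col]])] <- NA
    bad <- bad | is.na(v)
    out[[col]] <- v
  }
  if (any(bad)) {
    inform(paste0("rejected ", sum(bad), " row(s) of ", schema, " at line(s): ",
                  paste(which(bad), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  out <- as_tibble(out)
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Write a pipeline table
#'
#' @param x Tibble in one of the standard schemas.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Attribute a prey delivery to a sex from field cues
#'
#' A delivery is attributed to the male if any male criterion holds: the
#' female was known to be on the nest, male vocalizations accompanied the
#' delivery, or the female was heard vocalizing off-nest while a second owl
#' entered the cavity. The mirrored cues attribute a delivery to the
#' female. If no criterion holds — or criteria for *both* sexes hold — the
#' delivery is `unknown` (conservative conflict policy).
#'
#' @param female_on_nest,male_vocal_delivery,female_vocal_off_nest Logical
#'   male-attribution cues (vectorised).
#' @param male_on_nest,female_vocal_delivery,male_vocal_off_nest Logical
#'   female-attribution cues.
#' @return Character vector in `c("male", "female", "unknown")`.
#' @export
#' @examples
#' attribute_sex(female_on_nest = TRUE)
#' attribute_sex()  # no cues -> unknown
attribute_sex <- function(female_on_nest = FALSE, male_vocal_delivery = FALSE,
                          female_vocal_off_nest = FALSE, male_on_nest = FALSE,
                          female_vocal_delivery = FALSE, male_vocal_off_nest = FALSE) {
  male_cue <- female_on_nest | male_vocal_delivery | female_vocal_off_nest
  female_cue <- male_on_nest | female_vocal_delivery | male_vocal_off_nest
  out <- rep("unknown", length(male_cue))
  out[male_cue & !female_cue] <- "male"
  out[female_cue & !male_cue] <- "female"
  out
}

#' Filter delivery observations to the analysis window
#'
#' Retains only complete 15-minute intervals beginning no later than 90
#' minutes after sunset (the boundary is inclusive: the protocol drops
#' observations *later than* 90 min). Intervals shorter than 15 min are
#' dropped as `incomplete`; longer intervals are dropped as `overlong`
#' rather than truncated; full intervals starting past 90 min are dropped
#' as `late`. Idempotent.
#'
#' @param obs Delivery-observation tibble (deliveries schema).
#' @return Filtered tibble with a named integer attribute `"drop_counts"`
#'   (`incomplete`, `overlong`, `late`).
#' @export
filter_observations <- function(obs) {
  incomplete <- obs$interval_minutes < 15
  overlong <- obs$interval_minutes > 15
  late <- !incomplete & !overlong & obs$minutes_after_sunset > 90
  keep <- !(incomplete | overlong | late)
  out <- obs[keep, , drop = FALSE]
  attr(out, "drop_counts") <- c(incomplete = sum(incomplete),
                                overlong = sum(overlong),
                                late = sum(late))
  out
}

#' Exclude nests with unknown fates
#'
#' Nests whose fate is unknown are removed from all analyses: their
#' productivity records are dropped and so are their delivery
#' observations. Failed nests with known fates stay; their observations
#' (all recorded before the failure by the field protocol) are retained.
#'
#' @param nests Nest-record tibble (nests schema).
#' @param obs Delivery-observation tibble.
#' @return A list with elements `nests` and `observations`.
#' @export
exclude_unknown_fate <- function(nests, obs) {
  keep_nests <- nests[nests$fate_known, , drop = FALSE]
  drop_ids <- nests$nest_id[!nests$fate_known]
  list(nests = keep_nests,
       observations = obs[!obs$nest_id %in% drop_ids, , drop = FALSE])
}

#' Flag stage-order violations in productivity records
#'
#' Clutch, brood and fledgling counts are recorded stage-wise, and partial
#' predation or abandonment legitimately shrinks later stages — but a later
#' stage can never exceed an earlier one. Rows violating
#' `fledglings <= brood <= clutch` (on the stages present) are flagged for
#' review rather than silently dropped.
#'
#' @param nests Nest-record tibble.
#' @return `nests` with a logical `consistent` column; inconsistent rows
#'   trigger a warning naming the nests.
#' @export
check_nest_consistency <- function(nests) {
  ok_bc <- is.na(nests$brood) | is.na(nests$clutch) | nests$brood <= nests$clutch
  ok_fb <- is.na(nests$fledglings) | is.na(nests$brood) | nests$fledglings <= nests$brood
  out <- mutate(nests, consistent = ok_bc & ok_fb)
  if (any(!out$consistent)) {
    warn(paste0("stage-order violations at nest(s): ",
                paste(out$nest_id[!out$consistent], collapse = ", ")))
  }
  out
}
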