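# Per fish-year residency metrics: arrival/departure timing, residence
# duration, detection days, residency index (RI), per-station local
# residency index (RI_stat), and station counts.
#
# Conventions: all dates are UTC calendar dates; day-of-year is 1-based;
# residence duration is the inclusive day count from the date of first to
# the date of last detection, which bounds RI at 1 for a fish detected every
# day of its residence.

#' 1-based day of year
#'
#' January 1 is day 1; December 31 is day 365 (366 in leap years).
#'
#' @param date A `Date` or `POSIXct` vector (POSIXct interpreted in UTC).
#' @return Integer day-of-year in 1..366.
#' @export
doy <- function(date) {
  if (inherits(date, "POSIXct")) date <- utc_date(date)
  as.POSIXlt(date)$yday + 1L
}

#' Residency index
#'
#' The number of days a fish was detected in the region divided by its
#' residence duration (inclusive days from first to last detection). Values
#' near 1 indicate frequent detection throughout the residence period;
#' values near 0 indicate use of areas outside receiver coverage.
#'
#' @param n_detection_days Distinct UTC dates with a detection (vectorised).
#' @param duration_days Inclusive residence duration in days.
#' @return RI values in (0, 1].
#' @export
residency_index <- function(n_detection_days, duration_days) {
  if (any(duration_days < 1)) stop_mt("duration_days must be >= 1")
  if (any(n_detection_days < 1 | n_detection_days > duration_days))
    stop_mt("n_detection_days must lie in [1, duration_days]")
  n_detection_days / duration_days
}

#' Per fish-year residence records
#'
#' One record per (fish, calendar year) with at least one detection in the
#' requested region: arrival (first detection), departure (last detection),
#' inclusive residence duration, number of distinct detection days, RI,
#' number of distinct stations, and whether the year is a return year
#' (a year after the fish's tagging year — arrival in the tagging year is
#' confounded by capture, so timing statistics use return years only).
#' Records with duration of `min_duration_days` or less are flagged
#' `included = FALSE` (the default keeps only durations strictly greater
#' than 5 days, screening out partial residence periods seen only while a
#' fish enters or leaves the array).
#'
#' @param detections Filtered detection table.
#' @param deployments Tag deployments (species and tagging year per fish).
#' @param stations Station table (region labels).
#' @param region Focal region (default `"wadden_sea"`).
#' @param min_duration_days Inclusion threshold, strict (default 5).
#' @return Tibble of residence records.
#' @export
residence_records <- function(detections, deployments, stations,
                              region = "wadden_sea",
                              min_duration_days = 5) {
  region <- match.arg(region, regions())
  reg_map <- unique(stations[, c("station_id", "region")])
  d <- dplyr::inner_join(detections, reg_map, by = "station_id")
  d <- d[d$region == region, ]
  d <- dplyr::inner_join(
    d, deployments[, c("tag_id", "fish_id", "species", "release_time")],
    by = "tag_id"
  )
  if (nrow(d) == 0) {
    return(tibble::tibble(fish_id = character(), species = character(),
                          year = integer(), region = character(),
                          arrival = as.POSIXct(character(), tz = "UTC"),
                          departure = as.POSIXct(character(), tz = "UTC"),
                          duration_days = integer(),
                          n_detection_days = integer(), RI = numeric(),
                          n_stations = integer(), is_return_year = logical(),
                          included = logical()))
  }
  d$year <- utc_year(d$timestamp)
  d$date <- utc_date(d$timestamp)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$species, .data$year),
    arrival = min(.data$timestamp),
    departure = max(.data$timestamp),
    n_detection_days = dplyr::n_distinct(.data$date),
    n_stations = dplyr::n_distinct(.data$station_id),
    tag_year = utc_year(dplyr::first(.data$release_time)),
    .groups = "drop"
  )
  out$region <- region
  out$duration_days <- as.integer(utc_date(out$departure) -
                                    utc_date(out$arrival)) + 1L
  out$RI <- residency_index(out$n_detection_days, out$duration_days)
  out$is_return_year <- out$year > out$tag_year
  out$included <- out$duration_days > min_duration_days
  out$tag_year <- NULL
  out[, c("fish_id", "species", "year", "region", "arrival", "departure",
          "duration_days", "n_detection_days", "RI", "n_stations",
          "is_return_year", "included")]
}

#' Per-station local residency index
#'
#' For each fish-year, the share of its detection days contributed by each
#' station: days detected at the station divided by total days detected
#' across the array that year. A fish detected at several stations on one
#' date contributes that date to each, so the per fish-year sum of RI_stat is
#' at least 1, with equality exactly when no date has multi-station
#' detections.
#'
#' @param detections Filtered detection table.
#' @param deployments Tag deployments (fish and species per tag).
#' @param stations Station table; only stations in `region` are considered.
#' @param region Focal region (default `"wadden_sea"`).
#' @return Tibble: fish_id, species, year, station_id, n_days_at_station,
#'   RI_stat.
#' @export
local_residency_index <- function(detections, deployments, stations,
                                  region = "wadden_sea") {
  region <- match.arg(region, regions())
  reg_map <- unique(stations[, c("station_id", "region")])
  d <- dplyr::inner_join(detections, reg_map, by = "station_id")
  d <- d[d$region == region, ]
  d <- dplyr::inner_join(d, deployments[, c("tag_id", "fish_id", "species")],
                         by = "tag_id")
  d$year <- utc_year(d$timestamp)
  d$date <- utc_date(d$timestamp)
  per_station <- dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$species, .data$year,
                    .data$station_id),
    n_days_at_station = dplyr::n_distinct(.data$date),
    .groups = "drop"
  )
  totals <- dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$year),
    n_detection_days = dplyr::n_distinct(.data$date),
    .groups = "drop"
  )
  out <- dplyr::left_join(per_station, totals, by = c("fish_id", "year"))
  out$RI_stat <- out$n_days_at_station / out$n_detection_days
  out$n_detection_days <- NULL
  out
}

#' Per-station median local residency index
#'
#' The median RI_stat per station across eligible fish-years (fish detected
#' for more than the minimum duration in that year). Stations visited by no
#' eligible fish are absent from the output, not zero. Pass the excluded
#' station ids from [exclude_stations()] to honour the damage/short-
#' deployment exclusion that scopes station-level analyses.
#'
#' @param usages Output of [local_residency_index()].
#' @param residence Output of [residence_records()] (supplies eligibility).
#' @param excluded_station_ids Character vector of stations to drop.
#' @param by_species Compute medians per species as well (default TRUE when a
#'   species column is present).
#' @return Tibble: station_id (and species), median_RI_stat, n_fish_years.
#' @export
station_medians <- function(usages, residence, excluded_station_ids = NULL,
                            by_species = "species" %in% names(usages)) {
  elig <- residence[residence$included, c("fish_id", "year")]
  u <- dplyr::semi_join(usages, elig, by = c("fish_id", "year"))
  if (!is.null(excluded_station_ids)) {
    u <- u[!u$station_id %in% excluded_station_ids, ]
  }
  grp_vars <- if (by_species) c("station_id", "species") else "station_id"
  out <- dplyr::summarise(
    dplyr::group_by(u, dplyr::across(dplyr::all_of(grp_vars))),
    median_RI_stat = stats::median(.data$RI_stat),
    n_fish_years = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Unique stations detected per fish-year
#'
#' The number of distinct receiver stations at which each fish was detected
#' in each year — a proxy for mobility within the array.
#'
#' @inheritParams local_residency_index
#' @return Tibble: fish_id, species, year, n_stations.
#' @export
station_counts <- function(detections, deployments, stations,
                           region = "wadden_sea") {
  region <- match.arg(region, regions())
  reg_map <- unique(stations[, c("station_id", "region")])
  d <- dplyr::inner_join(detections, reg_map, by = "station_id")
  d <- d[d$region == region, ]
  d <- dplyr::inner_join(d, deployments[, c("tag_id", "fish_id", "species")],
                         by = "tag_id")
  d$year <- utc_year(d$timestamp)
  dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$species, .data$year),
    n_stations = dplyr::n_distinct(.data$station_id),
    .groups = "drop"
  )
}
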