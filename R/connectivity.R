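# Regional connectivity: cross-region movement events, direction relative to
# the focal region, weekly/monthly presence summaries, and the aggregated
# origin-destination graph.

#' Classify movement direction relative to a focal region
#'
#' A pure function of the two region labels: outbound when the origin is the
#' focal region, inbound when the destination is, external otherwise. Equal
#' origin and destination regions are an error (not a movement).
#'
#' @param origin_region,destination_region Region labels (vectorised).
#' @param focal_region The focal region (default `"wadden_sea"`).
#' @return Character vector: `"outbound_from_focal"`, `"inbound_to_focal"`,
#'   or `"external"`.
#' @export
classify_direction <- function(origin_region, destination_region,
                               focal_region = "wadden_sea") {
  focal_region <- match.arg(focal_region, regions())
  bad <- !origin_region %in% regions() | !destination_region %in% regions()
  if (any(bad)) stop_mt("unknown region label in direction classification")
  if (any(origin_region == destination_region))
    stop_mt("origin and destination regions must differ")
  ifelse(origin_region == focal_region, "outbound_from_focal",
         ifelse(destination_region == focal_region, "inbound_to_focal",
                "external"))
}

#' Extract cross-region movement events
#'
#' Scans each fish's detections chronologically; every adjacent pair whose
#' regions differ yields one movement event whose origin is the last
#' detection in the previous region and whose destination is the first
#' detection in the new region. No minimum displacement or speed filter is
#' applied. The event year is the calendar year of arrival at the
#' destination.
#'
#' @param detections Filtered detection table.
#' @param stations Station table (region labels).
#' @param deployments Optional tag deployments; when given, events carry
#'   `fish_id` and `species`.
#' @param focal_region Focal region for the direction classification.
#' @return Tibble of movement events.
#' @export
extract_movements <- function(detections, stations, deployments = NULL,
                              focal_region = "wadden_sea") {
  reg_map <- unique(stations[, c("station_id", "region")])
  d <- dplyr::inner_join(detections, reg_map, by = "station_id")
  d <- d[order(d$tag_id, d$timestamp, d$station_id), ]
  n <- nrow(d)
  empty <- tibble::tibble(
    tag_id = character(), origin_station = character(),
    destination_station = character(), origin_region = character(),
    destination_region = character(),
    t_origin = as.POSIXct(character(), tz = "UTC"),
    t_destination = as.POSIXct(character(), tz = "UTC"),
    direction = character(), year = integer()
  )
  if (n < 2) return(empty)
  same_tag <- d$tag_id[-1] == d$tag_id[-n]
  changed <- same_tag & d$region[-1] != d$region[-n]
  i <- which(changed)          # origin index; destination is i + 1
  if (length(i) == 0) return(empty)
  ev <- tibble::tibble(
    tag_id = d$tag_id[i],
    origin_station = d$station_id[i],
    destination_station = d$station_id[i + 1],
    origin_region = d$region[i],
    destination_region = d$region[i + 1],
    t_origin = d$timestamp[i],
    t_destination = d$timestamp[i + 1],
    direction = classify_direction(d$region[i], d$region[i + 1], focal_region),
    year = utc_year(d$timestamp[i + 1])
  )
  if (!is.null(deployments)) {
    ev <- dplyr::left_join(
      ev, deployments[, c("tag_id", "fish_id", "species")], by = "tag_id"
    )
    ev <- ev[, c("fish_id", "species", setdiff(names(ev), c("fish_id", "species")))]
  }
  ev
}

#' Unique-fish presence per region and period
#'
#' Counts distinct fish per region, period (ISO week `"2021-W23"` or calendar
#' month `"2021-06"`) and species. A fish detected in several regions within
#' one period is counted once in each.
#'
#' @param detections Filtered detection table.
#' @param stations Station table (region labels).
#' @param deployments Tag deployments (species per tag).
#' @param granularity `"week"` (ISO-8601 weeks) or `"month"`.
#' @return Tibble: region, period, species, n_unique_fish.
#' @export
presence_summary <- function(detections, stations, deployments,
                             granularity = c("week", "month")) {
  granularity <- match.arg(granularity)
  reg_map <- unique(stations[, c("station_id", "region")])
  d <- dplyr::inner_join(detections, reg_map, by = "station_id")
  d <- dplyr::inner_join(d, deployments[, c("tag_id", "fish_id", "species")],
                         by = "tag_id")
  fmt <- if (granularity == "week") "%G-W%V" else "%Y-%m"
  d$period <- format(utc_date(d$timestamp), fmt)
  dplyr::summarise(
    dplyr::group_by(d, .data$region, .data$period, .data$species),
    n_unique_fish = dplyr::n_distinct(.data$fish_id),
    .groups = "drop"
  )
}

#' Relative monthly presence across regions
#'
#' Normalises monthly unique-fish counts per species across regions within
#' each month: the share of that month's detected individuals (region
#' overlaps allowed, so shares are of the region-count total).
#'
#' @param presence Output of [presence_summary()] at month granularity.
#' @return The presence table with an added `share` column.
#' @export
relative_presence <- function(presence) {
  out <- dplyr::group_by(presence, .data$species, .data$period)
  out <- dplyr::mutate(out, share = .data$n_unique_fish /
                         sum(.data$n_unique_fish))
  dplyr::ungroup(out)
}

#' Aggregate movement events into a weighted edge list
#'
#' Edges originate at the station where a large-scale movement started and
#' end either at the destination station or (coarser) the destination region.
#' Edge weights are event multiplicities, so weights sum to the number of
#' events.
#'
#' @param events Output of [extract_movements()].
#' @param by `"destination_station"` (default) or `"destination_region"`.
#' @return Tibble edge list with `weight`.
#' @export
connectivity_graph <- function(events, by = c("destination_station",
                                              "destination_region")) {
  by <- match.arg(by)
  if (nrow(events) == 0) {
    return(tibble::tibble(origin_station = character(),
                          destination = character(), weight = integer()))
  }
  g <- dplyr::summarise(
    dplyr::group_by(events, .data$origin_station,
                    destination = .data[[by]], .data$origin_region,
                    .data$destination_region, .data$direction),
    weight = dplyr::n(),
    .groups = "drop"
  )
  g
}
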