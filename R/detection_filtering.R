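# False-detection filter cascade.
#
# Rules are applied in a fixed, documented order:
#   predeployment -> duplicates -> min_delay -> singletons_24h -> mortality
# Duplicates must precede the min-delay scan: an exact duplicate has gap 0
# and must not consume the scan against the last retained record. Every
# filter only removes records, and the report reconciles counts exactly.

filter_result <- function(detections, removed, extra = list()) {
  c(list(detections = detections, removed = removed), extra)
}

#' Remove detections recorded before tag deployment
#'
#' A detection timestamped exactly at the release time is retained ("prior
#' to" is read strictly).
#'
#' @param detections Detection table.
#' @param deployments Tag deployments; every tag appearing in `detections`
#'   must have a deployment record, otherwise an error lists the offenders.
#' @return List with `detections` (retained rows) and `removed` (count).
#' @export
filter_predeployment <- function(detections, deployments) {
  unknown <- setdiff(unique(detections$tag_id), deployments$tag_id)
  if (length(unknown) > 0)
    stop_mt("detections reference tags with no deployment record: ",
            paste(unknown, collapse = ", "))
  rel <- deployments$release_time[match(detections$tag_id, deployments$tag_id)]
  keep <- detections$timestamp >= rel
  filter_result(detections[keep, ], sum(!keep))
}

#' Remove exact duplicate detections
#'
#' Keeps exactly one record per identical (tag, station, timestamp) triple.
#' Identical (tag, timestamp) pairs heard at *different* stations are
#' physically valid (overlapping ranges) and are retained, but counted in the
#' result as `cross_station_simultaneities`.
#'
#' @param detections Detection table, sorted.
#' @return List with `detections`, `removed`, and
#'   `cross_station_simultaneities` (count of tag-time instants heard at more
#'   than one station).
#' @export
filter_duplicates <- function(detections) {
  dup <- duplicated(detections[, c("tag_id", "station_id", "timestamp")])
  out <- detections[!dup, ]
  tt <- paste(out$tag_id, as.numeric(out$timestamp))
  simult <- sum(table(unique(data.frame(tt = tt, st = out$station_id))$tt) > 1)
  filter_result(out, sum(dup),
                list(cross_station_simultaneities = unname(simult)))
}

#' Remove detections violating the minimum transmission delay
#'
#' Per (tag, station), scanning chronologically, a record is removed when its
#' gap to the previously *retained* record at that tag and station is
#' positive but smaller than the tag's minimum transmission delay: a coded
#' tag cannot emit twice within that interval, so the later record of each
#' violating pair must be false. Zero gaps are left alone (exact duplicates
#' are handled by [filter_duplicates()], which must run first).
#'
#' @param detections Detection table.
#' @param deployments Tag deployments supplying `min_delay_s` per tag.
#' @return List with `detections` and `removed`.
#' @export
filter_min_delay <- function(detections, deployments) {
  idx <- match(detections$tag_id, deployments$tag_id)
  if (anyNA(idx))
    stop_mt("missing min_delay for tag(s): ",
            paste(unique(detections$tag_id[is.na(idx)]), collapse = ", "))
  min_delay <- deployments$min_delay_s[idx]
  ord <- order(detections$tag_id, detections$station_id, detections$timestamp)
  d <- detections[ord, ]
  md <- min_delay[ord]
  t <- as.numeric(d$timestamp)
  grp <- paste(d$tag_id, d$station_id)
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap <- c(NA_real_, diff(t))
  gap[new_grp] <- NA_real_
  keep <- rep(TRUE, nrow(d))
  suspicious <- !is.na(gap) & gap > 0 & gap < md
  if (any(suspicious)) {
    # only groups containing a raw violation need the sequential scan
    bad_groups <- unique(grp[suspicious])
    for (g in bad_groups) {
      rows <- which(grp == g)
      last_kept <- t[rows[1]]
      m <- md[rows[1]]
      for (r in rows[-1]) {
        delta <- t[r] - last_kept
        if (delta > 0 && delta < m) {
          keep[r] <- FALSE
        } else {
          last_kept <- t[r]
        }
      }
    }
  }
  out <- detections[ord[keep], ]
  out <- out[order(out$tag_id, out$timestamp, out$station_id), ]
  filter_result(out, sum(!keep))
}

#' Remove 24-hour singleton detections
#'
#' A record is removed iff no other record of the same tag at the same
#' station lies within a 24 h window either side of it. Evaluation is
#' simultaneous over this rule's input (a record cannot be "rescued" by a
#' neighbour that this same rule removes, nor by detections at other
#' stations).
#'
#' @param detections Detection table.
#' @param window_s Window half-width in seconds (default 24 h).
#' @return List with `detections` and `removed`.
#' @export
filter_singletons_24h <- function(detections, window_s = 86400) {
  ord <- order(detections$tag_id, detections$station_id, detections$timestamp)
  d <- detections[ord, ]
  t <- as.numeric(d$timestamp)
  grp <- paste(d$tag_id, d$station_id)
  n <- nrow(d)
  if (n == 0) return(filter_result(d, 0L))
  same_prev <- c(FALSE, grp[-1] == grp[-n])
  gap_prev <- c(NA_real_, diff(t))
  near_prev <- same_prev & gap_prev <= window_s
  near_next <- c(near_prev[-1], FALSE)
  keep <- near_prev | near_next
  out <- detections[ord[keep], ]
  out <- out[order(out$tag_id, out$timestamp, out$station_id), ]
  filter_result(out, sum(!keep))
}

#' Remove detections of fish that died during the study
#'
#' Mortality identification is input-driven: a table of fish known to have
#' died (tag recoveries or inspection of detection profiles). The default
#' mode removes *all* records of listed fish; mode `"after_death"` removes
#' only records after the listed death time (records of fish without a death
#' time are removed entirely in either mode).
#'
#' @param detections Detection table.
#' @param mortality Tibble with `fish_id` and optionally `death_time`.
#' @param deployments Tag deployments (maps fish to tags).
#' @param mode `"all"` (default) or `"after_death"`.
#' @return List with `detections`, `removed`, and `fish` (the fish acted on).
#' @export
remove_mortality <- function(detections, mortality, deployments,
                             mode = c("all", "after_death")) {
  mode <- match.arg(mode)
  if (is.null(mortality) || nrow(mortality) == 0)
    return(filter_result(detections, 0L, list(fish = character(0))))
  unknown <- setdiff(mortality$fish_id, deployments$fish_id)
  if (length(unknown) > 0)
    warning("mortality table lists unknown fish: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  mort <- mortality[mortality$fish_id %in% deployments$fish_id, , drop = FALSE]
  tags <- deployments$tag_id[match(mort$fish_id, deployments$fish_id)]
  if (mode == "all" || !"death_time" %in% names(mort)) {
    keep <- !detections$tag_id %in% tags
  } else {
    cutoff <- rep(as.POSIXct(NA, tz = "UTC"), nrow(detections))
    m <- match(detections$tag_id, tags)
    cutoff[!is.na(m)] <- mort$death_time[m[!is.na(m)]]
    keep <- is.na(m) | (!is.na(cutoff) & detections$timestamp <= cutoff)
  }
  filter_result(detections[keep, ], sum(!keep), list(fish = mort$fish_id))
}

#' Flag stations excluded from occurrence and station-level analyses
#'
#' Stations that incurred damage or whose total deployment span is shorter
#' than `min_days` (default 90, strictly) are excluded from occurrence maps
#' and per-station medians. Their detections are *not* dropped from
#' arrival/departure timing — exclusion scope is per analysis, so this
#' returns the partition and (optionally) the detection subset rather than
#' mutating the dataset.
#'
#' @param stations Station deployment table (possibly several rows per
#'   station; spans are summed and damage flags OR-ed per station).
#' @param detections Optional detection table to subset.
#' @param min_days Minimum total deployment span in days (default 90).
#' @return List with `stations` (retained station table rows), `excluded`
#'   (tibble of station_id and reason), and `detections` (subset at retained
#'   stations, when supplied).
#' @export
exclude_stations <- function(stations, detections = NULL, min_days = 90) {
  per <- dplyr::summarise(
    dplyr::group_by(stations, .data$station_id),
    damaged = any(.data$damaged),
    span_days = sum(as.numeric(difftime(.data$active_end, .data$active_start,
                                        units = "days"))),
    .groups = "drop"
  )
  per$excluded <- per$damaged | per$span_days < min_days
  per$reason <- ifelse(per$damaged, "damaged",
                       ifelse(per$span_days < min_days, "short_deployment", NA))
  excluded <- per[per$excluded, c("station_id", "reason")]
  kept <- stations[!stations$station_id %in% excluded$station_id, ]
  out <- list(stations = kept, excluded = tibble::as_tibble(excluded))
  if (!is.null(detections)) {
    out$detections <- detections[!detections$station_id %in% excluded$station_id, ]
  }
  out
}

#' Apply the full false-detection filter cascade
#'
#' Runs, in order: [filter_predeployment()], [filter_duplicates()],
#' [filter_min_delay()], [filter_singletons_24h()], [remove_mortality()].
#' Station exclusions are *computed* for the report (they scope occurrence
#' and station-median analyses) but do not remove detections here. The
#' report's removal counts reconcile exactly with input minus output.
#'
#' @param detections Detection table.
#' @param deployments Tag deployments.
#' @param stations Optional station table (for the exclusion report).
#' @param mortality Optional mortality table.
#' @param mortality_mode Passed to [remove_mortality()].
#' @param station_min_days Passed to [exclude_stations()].
#' @return List with `detections` (filtered) and `report` (a `filter_report`
#'   list: rule order, per-rule examined/removed counts, mortality fish,
#'   station exclusions, simultaneity count).
#' @export
apply_filters <- function(detections, deployments, stations = NULL,
                          mortality = NULL, mortality_mode = "all",
                          station_min_days = 90) {
  n_in <- nrow(detections)
  rules <- list()
  r1 <- filter_predeployment(detections, deployments)
  rules$predeployment <- c(examined = n_in, removed = r1$removed)
  r2 <- filter_duplicates(r1$detections)
  rules$duplicates <- c(examined = nrow(r1$detections), removed = r2$removed)
  r3 <- filter_min_delay(r2$detections, deployments)
  rules$min_delay <- c(examined = nrow(r2$detections), removed = r3$removed)
  r4 <- filter_singletons_24h(r3$detections)
  rules$singletons_24h <- c(examined = nrow(r3$detections), removed = r4$removed)
  r5 <- remove_mortality(r4$detections, mortality, deployments,
                         mode = mortality_mode)
  rules$mortality <- c(examined = nrow(r4$detections), removed = r5$removed)

  rule_tbl <- tibble::tibble(
    rule = names(rules),
    examined = unname(vapply(rules, `[[`, numeric(1), "examined")),
    removed = unname(vapply(rules, `[[`, numeric(1), "removed"))
  )
  report <- structure(list(
    order = names(rules),
    rules = rule_tbl,
    n_input = n_in,
    n_output = nrow(r5$detections),
    cross_station_simultaneities = r2$cross_station_simultaneities,
    mortality_fish = r5$fish,
    station_exclusions = if (!is.null(stations))
      exclude_stations(stations, min_days = station_min_days)$excluded
    else NULL
  ), class = "filter_report")
  stopifnot(sum(rule_tbl$removed) == n_in - nrow(r5$detections))
  list(detections = r5$detections, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("False-detection filter report\n")
  cat(sprintf("  input: %d records, output: %d records\n", x$n_input, x$n_output))
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %-16s examined %8d  removed %6d\n",
                x$rules$rule[i], x$rules$examined[i], x$rules$removed[i]))
  }
  cat(sprintf("  cross-station simultaneities retained: %d\n",
              x$cross_station_simultaneities))
  if (!is.null(x$station_exclusions) && nrow(x$station_exclusions) > 0)
    cat(sprintf("  stations excluded from occurrence analyses: %d\n",
                nrow(x$station_exclusions)))
  invisible(x)
}

#' Serialise a filter report to JSON
#'
#' @param report A `filter_report` from [apply_filters()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Heuristic mortality flagger (optional convenience)
#'
#' Flags fish whose detections show uninterrupted single-station presence for
#' at least `min_run_days` consecutive detection days — the signature of a
#' tag lying on the seabed near one receiver. A convenience for screening;
#' the cascade itself takes mortality as an input table.
#'
#' @param detections Filtered or raw detection table.
#' @param deployments Tag deployments.
#' @param min_run_days Minimum consecutive single-station detection days
#'   (default 60).
#' @return Tibble of flagged `fish_id` with the run start (candidate death
#'   time) and run length.
#' @export
flag_mortality_candidates <- function(detections, deployments,
                                      min_run_days = 60) {
  d <- dplyr::inner_join(detections,
                         deployments[, c("tag_id", "fish_id")], by = "tag_id")
  d$date <- utc_date(d$timestamp)
  daily <- dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$date),
    n_stations = dplyr::n_distinct(.data$station_id),
    station = dplyr::first(.data$station_id),
    .groups = "drop"
  )
  daily <- daily[order(daily$fish_id, daily$date), ]
  out <- list()
  for (f in unique(daily$fish_id)) {
    dd <- daily[daily$fish_id == f, ]
    # runs of consecutive days at a single station
    run_id <- cumsum(c(TRUE, !(diff(as.numeric(dd$date)) == 1 &
                                 dd$station[-1] == dd$station[-nrow(dd)] &
                                 dd$n_stations[-1] == 1)))
    for (r in split(seq_len(nrow(dd)), run_id)) {
      if (length(r) >= min_run_days && all(dd$n_stations[r] == 1)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          fish_id = f,
          candidate_death = as.POSIXct(paste(dd$date[r[1]], "00:00:00"),
                                       tz = "UTC"),
          run_days = length(r)
        )
        break
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(fish_id = character(),
                          candidate_death = as.POSIXct(character(), tz = "UTC"),
                          run_days = integer()))
  }
  dplyr::bind_rows(out)
}
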