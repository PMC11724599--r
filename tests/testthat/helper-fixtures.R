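# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive brute-force procedures so they share no code path with the
# implementation they check.

utc <- function(x) as.POSIXct(x, tz = "UTC")

det_tbl <- function(tag_id, station_id, timestamp) {
  tibble::tibble(tag_id = tag_id, station_id = station_id,
                 timestamp = utc(timestamp))
}

dep_tbl <- function(tag_id, fish_id = paste0("f_", tag_id),
                    species = "thicklip",
                    release_time = "2021-01-01 00:00:00",
                    min_delay_s = 60, max_delay_s = 120,
                    length_cm = 50) {
  tibble::tibble(fish_id = fish_id, tag_id = tag_id, species = species,
                 release_time = utc(release_time),
                 release_x_m = 0, release_y_m = 0,
                 min_delay_s = min_delay_s, max_delay_s = max_delay_s,
                 length_cm = length_cm)
}

st_tbl <- function(station_id, region = "wadden_sea",
                   x_m = 0, y_m = 0, array_name = "A",
                   active_start = "2021-01-01 00:00:00",
                   active_end = "2023-12-31 23:59:59",
                   damaged = FALSE) {
  tibble::tibble(station_id = station_id, array_name = array_name,
                 region = region, x_m = x_m, y_m = y_m,
                 active_start = utc(active_start), active_end = utc(active_end),
                 damaged = damaged)
}

# small, fast simulation: coarse tag delay keeps transmission counts low
# without touching any day-based quantity
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_fish = c(thicklip = 6L, thinlip = 4L),
                   n_years = 2, min_delay_s = 1800, max_delay_s = 3600,
                   mortality_fraction = 0)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# random detection tables with deliberate collisions (duplicates, sub-delay
# gaps, singletons) so every filter has work to do
random_detections <- function(n, seed, n_tags = 4, n_stations = 5,
                              min_delay_s = 60) {
  set.seed(seed)
  tags <- sprintf("T%02d", seq_len(n_tags))
  stations <- sprintf("S%02d", seq_len(n_stations))
  base <- utc("2021-06-01 00:00:00")
  # cluster times so short gaps and duplicates arise naturally
  t <- as.numeric(base) +
    sample(0:(30 * 86400), n, replace = TRUE) %/% 600 * 600 +
    sample(c(0, 1, 5, 30, 59, 61, 300), n, replace = TRUE)
  det <- tibble::tibble(
    tag_id = sample(tags, n, replace = TRUE),
    station_id = sample(stations, n, replace = TRUE),
    timestamp = as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
  )
  det[order(det$tag_id, det$timestamp, det$station_id), ]
}

# ---- brute-force filter oracles ---------------------------------------------

bf_predeployment <- function(det, dep) {
  keep <- vapply(seq_len(nrow(det)), function(i) {
    rel <- dep$release_time[dep$tag_id == det$tag_id[i]]
    det$timestamp[i] >= rel
  }, logical(1))
  det[keep, ]
}

bf_duplicates <- function(det) {
  key <- paste(det$tag_id, det$station_id, as.numeric(det$timestamp))
  det[!duplicated(key), ]
}

# repeatedly find and delete the later record of the first remaining
# violating adjacent pair — quadratic and order-free by construction
bf_min_delay <- function(det, dep) {
  d <- det[order(det$tag_id, det$station_id, det$timestamp), ]
  repeat {
    t <- as.numeric(d$timestamp)
    md <- dep$min_delay_s[match(d$tag_id, dep$tag_id)]
    grp <- paste(d$tag_id, d$station_id)
    viol <- which(grp[-1] == grp[-nrow(d)] &
                    diff(t) > 0 & diff(t) < md[-1])
    if (length(viol) == 0) break
    d <- d[-(viol[1] + 1), ]
  }
  d[order(d$tag_id, d$timestamp, d$station_id), ]
}

bf_singletons <- function(det, window_s = 86400) {
  n <- nrow(det)
  keep <- vapply(seq_len(n), function(i) {
    same <- det$tag_id == det$tag_id[i] & det$station_id == det$station_id[i]
    dt <- abs(as.numeric(det$timestamp) - as.numeric(det$timestamp[i]))
    any(same & dt <= window_s & seq_len(n) != i)
  }, logical(1))
  det[keep, ]
}

sort_det <- function(det) {
  out <- det[order(det$tag_id, det$timestamp, det$station_id), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

expect_same_detections <- function(a, b) {
  expect_equal(as.data.frame(sort_det(a)), as.data.frame(sort_det(b)),
               ignore_attr = TRUE)
}

# ---- geometry oracles -------------------------------------------------------

# gift-wrapping (Jarvis march) convex hull, independent of grDevices::chull
bf_hull <- function(p) {
  p <- unique(p)
  n <- nrow(p)
  start <- which.min(p[, 2] + p[, 1] * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (p[nxt, 1] - p[cur, 1]) * (p[j, 2] - p[cur, 2]) -
        (p[nxt, 2] - p[cur, 2]) * (p[j, 1] - p[cur, 1])
      d_nxt <- sum((p[nxt, ] - p[cur, ])^2)
      d_j <- sum((p[j, ] - p[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_j > d_nxt)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) break
  }
  p[hull, , drop = FALSE]
}

shoelace <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

# Monte-Carlo area of (convex hull minus axis-aligned rectangle), km^2
mc_clipped_area <- function(hull_ccw, rect, n_samples = 1e6, seed = 1) {
  set.seed(seed)
  xr <- range(hull_ccw[, 1]); yr <- range(hull_ccw[, 2])
  px <- stats::runif(n_samples, xr[1], xr[2])
  py <- stats::runif(n_samples, yr[1], yr[2])
  inside <- rep(TRUE, n_samples)
  n <- nrow(hull_ccw)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    inside <- inside &
      ((hull_ccw[j, 1] - hull_ccw[i, 1]) * (py - hull_ccw[i, 2]) -
         (hull_ccw[j, 2] - hull_ccw[i, 2]) * (px - hull_ccw[i, 1])) >= 0
  }
  in_rect <- px >= rect[1] & px <= rect[2] & py >= rect[3] & py <= rect[4]
  box_area <- diff(xr) * diff(yr)
  mean(inside & !in_rect) * box_area / 1e6
}

# RI/RI_stat algebra checks shared by the residency and acceptance suites:
# RI in (0, 1]; per fish-year sum of RI_stat >= 1 with equality exactly when
# no date has multi-station detections
check_ri_algebra <- function(ds, filtered) {
  rr <- residence_records(filtered, ds$deployments, ds$stations)
  testthat::expect_true(all(rr$RI > 0 & rr$RI <= 1))
  u <- local_residency_index(filtered, ds$deployments, ds$stations)
  sums <- tapply(u$RI_stat, paste(u$fish_id, u$year), sum)
  testthat::expect_true(all(sums >= 1 - 1e-12))
  d <- dplyr::inner_join(filtered, ds$deployments[, c("tag_id", "fish_id")],
                         by = "tag_id")
  d <- d[d$station_id %in%
           ds$stations$station_id[ds$stations$region == "wadden_sea"], ]
  d$year <- as.integer(format(d$timestamp, "%Y", tz = "UTC"))
  d$date <- as.Date(d$timestamp, tz = "UTC")
  per_day <- dplyr::summarise(
    dplyr::group_by(d, fish_id, year, date),
    n_st = dplyr::n_distinct(station_id), .groups = "drop")
  multi <- dplyr::summarise(
    dplyr::group_by(per_day, fish_id, year),
    multi = any(n_st > 1), .groups = "drop")
  key <- paste(multi$fish_id, multi$year)
  for (i in seq_len(nrow(multi))) {
    s <- sums[[key[i]]]
    if (multi$multi[i]) testthat::expect_gt(s, 1)
    else testthat::expect_equal(unname(s), 1)
  }
  list(n_fish_years = length(sums), n_multi = sum(multi$multi))
}
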