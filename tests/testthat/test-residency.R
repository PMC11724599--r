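# Residency metrics: day-of-year convention, the residence-record formulae,
# RI bounds, RI_stat algebra, station medians, and simulation cross-checks.

test_that("day-of-year is 1-based with the documented anchor dates", {
  expect_equal(doy(as.Date("2022-06-07")), 158)  # non-leap June 7
  expect_equal(doy(as.Date("2022-01-01")), 1)
  expect_equal(doy(as.Date("2024-12-31")), 366)  # leap year
  expect_equal(doy(as.Date("2022-12-31")), 365)
  expect_equal(doy(utc("2022-06-07 23:59:59")), 158)
})

test_that("residence records follow the inclusive-duration formula", {
  dep <- dep_tbl("T1", "f1", release_time = "2021-01-01 00:00:00")
  st <- st_tbl("S1")
  # detections on days 10, 14 and 20 of the year
  det <- det_tbl(rep("T1", 3), rep("S1", 3),
                 c("2021-01-10 08:00:00", "2021-01-14 12:00:00",
                   "2021-01-20 18:00:00"))
  rr <- residence_records(det, dep, st)
  expect_equal(nrow(rr), 1)
  expect_equal(doy(rr$arrival), 10)
  expect_equal(doy(rr$departure), 20)
  expect_equal(rr$duration_days, 11L)      # (20 - 10) + 1
  expect_equal(rr$n_detection_days, 3L)
  expect_equal(rr$RI, 3 / 11)
  expect_false(rr$is_return_year)          # tagged in 2021
  expect_true(rr$included)                 # 11 > 5

  # a single detection gives duration 1 and is excluded under the default
  one <- det_tbl("T1", "S1", "2021-05-01 10:00:00")
  rr1 <- residence_records(one, dep, st)
  expect_equal(rr1$duration_days, 1L)
  expect_equal(rr1$RI, 1)
  expect_false(rr1$included)

  # exactly 5 days is still excluded (strict > 5)
  five <- det_tbl(rep("T1", 2), rep("S1", 2),
                  c("2021-05-01 10:00:00", "2021-05-05 10:00:00"))
  expect_false(residence_records(five, dep, st)$included)
  six <- det_tbl(rep("T1", 2), rep("S1", 2),
                 c("2021-05-01 10:00:00", "2021-05-06 10:00:00"))
  expect_true(residence_records(six, dep, st)$included)
})

test_that("residency index is bounded and validates its inputs", {
  expect_equal(residency_index(10, 10), 1)
  expect_equal(residency_index(4, 20), 0.2)
  expect_error(residency_index(0, 10), "n_detection_days")
  expect_error(residency_index(11, 10), "n_detection_days")
  expect_error(residency_index(1, 0), "duration_days")
})

test_that("RI_stat shares detection days across stations", {
  dep <- dep_tbl("T1", "f1")
  st <- dplyr::bind_rows(st_tbl("A"), st_tbl("B"), st_tbl("C"))
  # 10 detection days, 4 at station A, 6 at B
  days <- sprintf("2021-06-%02d 10:00:00", 1:10)
  det <- det_tbl(rep("T1", 10), c(rep("A", 4), rep("B", 6)), days)
  u <- local_residency_index(det, dep, st)
  expect_equal(u$RI_stat[u$station_id == "A"], 0.4)
  expect_equal(u$RI_stat[u$station_id == "B"], 0.6)
  expect_equal(sum(u$RI_stat), 1)

  # single-station fish
  u1 <- local_residency_index(det_tbl("T1", "A", "2021-06-01 10:00:00"),
                              dep, st)
  expect_equal(u1$RI_stat, 1)

  # two stations on the same single day: each share is 1, the sum is 2
  both <- det_tbl(rep("T1", 2), c("A", "B"),
                  rep("2021-06-01 10:00:00", 2))
  u2 <- local_residency_index(both, dep, st)
  expect_equal(sort(u2$RI_stat), c(1, 1))
  expect_equal(sum(u2$RI_stat), 2)
})

test_that("station medians cover eligible fish-years only", {
  u <- tibble::tibble(
    fish_id = c("f1", "f2", "f3", "f4"),
    species = "thicklip",
    year = 2022L,
    station_id = c("A", "A", "A", "B"),
    n_days_at_station = 1L,
    RI_stat = c(0.2, 0.4, 0.9, 0.5)
  )
  res <- tibble::tibble(fish_id = c("f1", "f2", "f3", "f4"), year = 2022L,
                        included = c(TRUE, TRUE, TRUE, FALSE))
  m <- station_medians(u, res)
  expect_equal(m$median_RI_stat[m$station_id == "A"], 0.4)
  # station B's only fish-year is ineligible: absent, not zero
  expect_false("B" %in% m$station_id)
  # excluded stations are dropped
  m2 <- station_medians(u, res, excluded_station_ids = "A")
  expect_equal(nrow(m2), 0)
})

test_that("RI_stat algebra holds on a synthetic cohort, both equality cases", {
  cfg <- tiny_config(seed = 41, n_fish = c(thicklip = 8L, thinlip = 4L))
  ds <- simulate_dataset(cfg)
  f <- apply_filters(ds$detections, ds$deployments)
  rr <- residence_records(f$detections, ds$deployments, ds$stations)
  expect_true(all(rr$RI > 0 & rr$RI <= 1))
  expect_true(all(rr$n_detection_days <= rr$duration_days))

  u <- local_residency_index(f$detections, ds$deployments, ds$stations)
  sums <- tapply(u$RI_stat, paste(u$fish_id, u$year), sum)
  expect_true(all(sums >= 1 - 1e-12))

  # per fish-year: sum == 1 iff no date has multi-station detections
  d <- dplyr::inner_join(f$detections,
                         ds$deployments[, c("tag_id", "fish_id")], "tag_id")
  d <- d[d$station_id %in%
           ds$stations$station_id[ds$stations$region == "wadden_sea"], ]
  d$year <- as.integer(format(d$timestamp, "%Y", tz = "UTC"))
  d$date <- as.Date(d$timestamp, tz = "UTC")
  per_day <- dplyr::summarise(
    dplyr::group_by(d, .data$fish_id, .data$year, .data$date),
    n_st = dplyr::n_distinct(.data$station_id), .groups = "drop")
  multi <- dplyr::summarise(
    dplyr::group_by(per_day, .data$fish_id, .data$year),
    multi = any(.data$n_st > 1), .groups = "drop")
  key <- paste(multi$fish_id, multi$year)
  for (i in seq_len(nrow(multi))) {
    s <- sums[[key[i]]]
    if (multi$multi[i]) expect_gt(s, 1) else expect_equal(unname(s), 1)
  }
})

test_that("estimated arrivals are never earlier than true arrivals", {
  cfg <- tiny_config(seed = 43, n_fish = c(thicklip = 10L, thinlip = 6L))
  ds <- simulate_dataset(cfg)
  f <- apply_filters(ds$detections, ds$deployments)
  rr <- residence_records(f$detections, ds$deployments, ds$stations)
  truth <- ds$truth$residence
  j <- dplyr::inner_join(rr, truth, by = c("fish_id", "year"))
  bias <- as.numeric(utc_date(j$arrival) - j$true_arrival)
  expect_true(all(bias >= 0))
  # at default detectability the median return-year bias is small
  ret <- j[j$is_return_year, ]
  expect_lte(median(as.numeric(utc_date(ret$arrival) - ret$true_arrival)), 3)
})

test_that("lowering detectability never increases detection days (coupled seed)", {
  # identical seed, trajectories, schedules and candidate geometry (same
  # d_max); only the midpoint range shrinks, so the detection probability is
  # pointwise lower and the RNG draws align one-to-one: detection sets nest.
  cfg_hi <- tiny_config(seed = 47, n_fish = c(thicklip = 6L), n_years = 1)
  cfg_lo <- tiny_config(seed = 47, n_fish = c(thicklip = 6L), n_years = 1,
                        d50_m = 60)
  ds_hi <- simulate_dataset(cfg_hi)
  ds_lo <- simulate_dataset(cfg_lo)
  days <- function(ds) {
    d <- ds$detections
    length(unique(paste(d$tag_id, as.Date(d$timestamp, tz = "UTC"))))
  }
  expect_lte(days(ds_lo), days(ds_hi))
  expect_lte(nrow(ds_lo$detections), nrow(ds_hi$detections))
  # nesting: every low-detectability record exists in the high set
  expect_equal(nrow(dplyr::anti_join(
    ds_lo$detections, ds_hi$detections,
    by = c("tag_id", "station_id", "timestamp"))), 0)
})
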