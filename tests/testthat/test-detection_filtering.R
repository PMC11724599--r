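# Filter cascade semantics: hand-computed fixtures for every rule, oracle
# equivalence on random data, idempotence, order sensitivity, conservation,
# and truth-labelled noise recovery.

test_that("pre-deployment filter is strict about 'prior to'", {
  dep <- dep_tbl("T1", release_time = "2021-06-01 12:00:00")
  det <- det_tbl(rep("T1", 3), rep("S1", 3),
                 c("2021-06-01 11:00:00",   # 1 h before release: removed
                   "2021-06-01 12:00:00",   # exactly at release: retained
                   "2021-06-01 13:00:00"))
  r <- filter_predeployment(det, dep)
  expect_equal(r$removed, 1)
  expect_equal(r$detections$timestamp,
               utc(c("2021-06-01 12:00:00", "2021-06-01 13:00:00")))
  # unknown tag is an error naming the offender
  bad <- det_tbl("T9", "S1", "2021-06-01 12:00:00")
  expect_error(filter_predeployment(bad, dep), "T9")
})

test_that("duplicate filter keeps one copy and counts cross-station simultaneity", {
  det <- det_tbl(c("T1", "T1", "T1", "T1"),
                 c("S1", "S1", "S1", "S2"),
                 c("2021-06-01 10:00:00", "2021-06-01 10:00:00",
                   "2021-06-01 10:05:00", "2021-06-01 10:05:00"))
  r <- filter_duplicates(det)
  expect_equal(r$removed, 1)
  expect_equal(nrow(r$detections), 3)
  # same tag, same second, two stations: both survive, counted once
  expect_equal(r$cross_station_simultaneities, 1)
  expect_equal(sum(r$detections$station_id == "S2"), 1)
})

test_that("min-delay scan removes against the last retained record", {
  dep <- dep_tbl("T1", min_delay_s = 60)
  # gaps: 30 s (violates), then 70 s from the *retained* first record
  det <- det_tbl(rep("T1", 3), rep("S1", 3),
                 c("2021-06-01 10:00:00", "2021-06-01 10:00:30",
                   "2021-06-01 10:01:10"))
  r <- filter_min_delay(det, dep)
  expect_equal(r$removed, 1)
  expect_equal(r$detections$timestamp,
               utc(c("2021-06-01 10:00:00", "2021-06-01 10:01:10")))
  # all gaps >= min delay: identity
  ok <- det_tbl(rep("T1", 3), rep("S1", 3),
                c("2021-06-01 10:00:00", "2021-06-01 10:01:00",
                  "2021-06-01 10:02:30"))
  expect_equal(filter_min_delay(ok, dep)$removed, 0)
  # the scan is per station: a 30 s gap across stations is fine
  cross <- det_tbl(rep("T1", 2), c("S1", "S2"),
                   c("2021-06-01 10:00:00", "2021-06-01 10:00:30"))
  expect_equal(filter_min_delay(cross, dep)$removed, 0)
  expect_error(filter_min_delay(det_tbl("T9", "S1", "2021-06-01 10:00:00"),
                                dep), "min_delay")
})

test_that("24 h singleton rule evaluates simultaneously", {
  # lone detection: removed
  one <- det_tbl("T1", "S1", "2021-06-01 10:00:00")
  expect_equal(nrow(filter_singletons_24h(one)$detections), 0)
  # 23 h apart: both retained
  near <- det_tbl(rep("T1", 2), rep("S1", 2),
                  c("2021-06-01 10:00:00", "2021-06-02 09:00:00"))
  expect_equal(filter_singletons_24h(near)$removed, 0)
  # 25 h apart and nothing else: each is alone in its window, both removed
  far <- det_tbl(rep("T1", 2), rep("S1", 2),
                 c("2021-06-01 10:00:00", "2021-06-02 11:00:00"))
  expect_equal(filter_singletons_24h(far)$removed, 2)
  # a neighbour at another station does not rescue a singleton
  other_station <- det_tbl(rep("T1", 2), c("S1", "S2"),
                           c("2021-06-01 10:00:00", "2021-06-01 11:00:00"))
  expect_equal(filter_singletons_24h(other_station)$removed, 2)
})

test_that("mortality removal supports remove-all and after-death modes", {
  dep <- dplyr::bind_rows(dep_tbl("T1", "f1"), dep_tbl("T2", "f2"))
  det <- det_tbl(rep(c("T1", "T2"), each = 3), rep("S1", 6),
                 rep(c("2021-06-01 10:00:00", "2021-06-10 10:00:00",
                       "2021-06-20 10:00:00"), 2))
  mort <- tibble::tibble(fish_id = "f1",
                         death_time = utc("2021-06-15 00:00:00"))
  all_mode <- remove_mortality(det, mort, dep, mode = "all")
  expect_equal(all_mode$removed, 3)
  expect_true(all(all_mode$detections$tag_id == "T2"))
  after <- remove_mortality(det, mort, dep, mode = "after_death")
  expect_equal(after$removed, 1)
  # empty table is the identity
  expect_equal(remove_mortality(det, NULL, dep)$removed, 0)
  # unknown fish warns but does not abort
  expect_warning(remove_mortality(det, tibble::tibble(fish_id = "ghost"), dep),
                 "unknown fish")
})

test_that("station exclusion uses damage and a strict 90-day span", {
  st <- dplyr::bind_rows(
    st_tbl("S89", active_start = "2021-04-01 00:00:00",
           active_end = "2021-06-29 00:00:00"),              # 89 d: excluded
    st_tbl("S90", active_start = "2021-04-01 00:00:00",
           active_end = "2021-06-30 00:00:00"),              # 90 d: retained
    st_tbl("SD", damaged = TRUE)                             # damaged: excluded
  )
  det <- det_tbl(rep("T1", 3), c("S89", "S90", "SD"),
                 rep("2021-06-01 10:00:00", 3))
  r <- exclude_stations(st, det)
  expect_setequal(r$excluded$station_id, c("S89", "SD"))
  expect_equal(r$excluded$reason[r$excluded$station_id == "S89"],
               "short_deployment")
  expect_equal(r$excluded$reason[r$excluded$station_id == "SD"], "damaged")
  expect_equal(r$detections$station_id, "S90")
  # brute-force partition on a random mixed set
  set.seed(2)
  n <- 50
  spans <- sample(30:200, n, replace = TRUE)
  stx <- st_tbl(sprintf("S%02d", 1:n),
                active_start = "2021-01-01 00:00:00",
                damaged = stats::runif(n) < 0.2)
  stx$active_end <- stx$active_start + spans * 86400
  rx <- exclude_stations(stx)
  manual <- stx$station_id[stx$damaged | spans < 90]
  expect_setequal(rx$excluded$station_id, manual)
})

test_that("each filter matches its brute-force oracle on random data", {
  for (seed in 1:8) {
    det <- random_detections(400, seed)
    dep <- dplyr::bind_rows(lapply(unique(det$tag_id), function(tg)
      dep_tbl(tg, release_time = "2021-06-03 00:00:00", min_delay_s = 60)))
    expect_same_detections(filter_predeployment(det, dep)$detections,
                           bf_predeployment(det, dep))
    expect_same_detections(filter_duplicates(det)$detections,
                           bf_duplicates(det))
    ded <- filter_duplicates(det)$detections
    expect_same_detections(filter_min_delay(ded, dep)$detections,
                           bf_min_delay(ded, dep))
    expect_same_detections(filter_singletons_24h(det)$detections,
                           bf_singletons(det))
  }
})

test_that("cascade order matters only where documented and is idempotent", {
  dep <- dep_tbl("T1", min_delay_s = 60, release_time = "2021-06-01 00:00:00")
  # crafted 6-record fixture: an exact duplicate pair, a sub-delay ghost,
  # a healthy pair, and one singleton far away
  det <- det_tbl(rep("T1", 6), rep("S1", 6),
                 c("2021-06-02 10:00:00", "2021-06-02 10:00:00",
                   "2021-06-02 10:00:30", "2021-06-02 10:02:00",
                   "2021-06-02 10:03:00", "2021-07-15 00:00:00"))
  r <- apply_filters(det, dep)
  # by hand: duplicate removed (1), ghost at +30 s removed (1), singleton
  # on July 15 removed (1); survivors are 10:00:00, 10:02:00, 10:03:00
  expect_equal(r$detections$timestamp,
               utc(c("2021-06-02 10:00:00", "2021-06-02 10:02:00",
                     "2021-06-02 10:03:00")))
  expect_equal(r$report$rules$removed,
               c(0, 1, 1, 1, 0))
  # idempotence: re-applying the cascade changes nothing
  r2 <- apply_filters(r$detections, dep)
  expect_same_detections(r2$detections, r$detections)
  expect_equal(sum(r2$report$rules$removed), 0)
  # conservation
  expect_equal(r$report$n_input - r$report$n_output,
               sum(r$report$rules$removed))
})

test_that("cascade removes all labelled noise and only rule-demanded true records", {
  cfg <- tiny_config(seed = 17, n_fish = c(thicklip = 5L, thinlip = 3L),
                     mortality_fraction = 0.3,
                     n_false_positives = 10, n_echo_duplicates = 10,
                     n_subdelay_ghosts = 10)
  ds <- simulate_dataset(cfg)
  noisy <- apply_filters(ds$detections, ds$deployments, ds$stations,
                         ds$mortality)
  # oracle: the cascade applied to the noise-free true records
  lab <- ds$truth$detection_labels
  clean <- sort_det(lab[lab$label == "true", c("tag_id", "station_id",
                                               "timestamp")])
  clean_f <- apply_filters(clean, ds$deployments, ds$stations, ds$mortality)
  expect_same_detections(noisy$detections, clean_f$detections)
  # clean input passes unchanged except for its own true singletons/mortality
  expect_equal(noisy$report$n_output, clean_f$report$n_output)
  # a no-noise, no-mortality dataset is untouched except true singletons
  cfg0 <- tiny_config(seed = 18, n_fish = c(thicklip = 3L))
  ds0 <- simulate_dataset(cfg0)
  r0 <- apply_filters(ds0$detections, ds0$deployments)
  expect_equal(r0$report$rules$removed[1:3], c(0, 0, 0))
})

test_that("the mortality heuristic flags simulated dead fish", {
  cfg <- tiny_config(seed = 23, n_fish = c(thicklip = 6L),
                     mortality_fraction = 0.5, n_years = 1)
  ds <- simulate_dataset(cfg)
  dead_fish <- ds$truth$fish$fish_id[ds$truth$fish$dead]
  expect_true(length(dead_fish) > 0)
  flagged <- flag_mortality_candidates(ds$detections, ds$deployments,
                                       min_run_days = 30)
  expect_true(all(dead_fish %in% flagged$fish_id))
})
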