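# Generator behaviour: determinism, array layout, the detection-range curve,
# trajectory degenerate cases, transmission scheduling, and noise injection.

test_that("default array has 90 focal stations and one freshwater receiver", {
  cfg <- simulation_config(seed = 3)
  st <- simulate_array(cfg)
  expect_equal(sum(st$region == "wadden_sea"), 90)
  expect_equal(sum(st$region == "fresh_water"), 1)
  expect_true(all(st$region %in% regions()))
  # same seed twice -> identical coordinates
  st2 <- simulate_array(cfg)
  expect_identical(st, st2)
  expect_error(simulate_array(simulation_config(n_wadden = 0, n_north_sea = 0,
                                                n_fresh = 0)),
               "zero stations")
})

test_that("detection-range curve passes through both anchors and is monotone", {
  expect_equal(detection_probability(149), 0.5, tolerance = 1e-12)
  expect_equal(detection_probability(610), 0.05, tolerance = 1e-12)
  p0 <- detection_probability(0)
  expect_gt(p0, 0.9)
  expect_lt(p0, 1)
  d <- seq(0, 2000, by = 10)
  expect_true(all(diff(detection_probability(d)) <= 0))
  # the analytic exponent reproduces an arbitrary configured tail probability
  expect_equal(detection_probability(890, d50_m = 310, d_max_m = 890,
                                     p_at_dmax = 0.1), 0.1, tolerance = 1e-12)
  expect_error(detection_probability(10, d50_m = 700, d_max_m = 610), "smaller")
  expect_error(detection_probability(-5), ">= 0")
})

test_that("degenerate trajectory settings behave as documented", {
  # full fidelity pins the walk to its seed station
  sp <- species_params("thicklip", 150, 0, 250, 0, 6000, 1, 1, 0)
  cfg <- tiny_config(seed = 5, n_fish = c(thicklip = 3L),
                     species = list(thicklip = sp), n_years = 1)
  ds <- simulate_fish(cfg, simulate_array(cfg))
  res <- ds$trajectories[ds$trajectories$state == "resident", ]
  per_fish <- tapply(res$station_id, res$fish_id, function(s) length(unique(s)))
  expect_true(all(per_fish == 1))
  # zero mortality -> no death times in truth
  expect_true(all(!ds$truth$fish$dead))
  expect_true(all(is.na(ds$truth$fish$death_time)))
})

test_that("fixed transmission delay makes same-station gaps exact multiples", {
  cfg <- tiny_config(seed = 8, n_fish = c(thicklip = 2L), n_years = 1,
                     min_delay_s = 60, max_delay_s = 60)
  ds <- simulate_dataset(cfg)
  d <- ds$detections
  gaps <- unlist(tapply(as.numeric(d$timestamp),
                        paste(d$tag_id, d$station_id),
                        function(t) diff(sort(t))))
  expect_true(length(gaps) > 0)
  expect_true(all(gaps %% 60 == 0))
  expect_true(all(gaps >= 60))
})

test_that("inactive stations hear nothing and the dataset is seed-deterministic", {
  cfg <- tiny_config(seed = 9, n_fish = c(thicklip = 2L), n_years = 1)
  st <- simulate_array(cfg)
  st$active_start <- utc("2030-01-01 00:00:00")
  st$active_end <- utc("2031-01-01 00:00:00")
  fish <- simulate_fish(cfg, st)
  dep <- mullettrack:::build_deployments(cfg, fish$truth$fish,
                                         fish$trajectories)
  det <- simulate_detections(cfg, st, fish$trajectories, dep)
  expect_equal(nrow(det$detections), 0)

  ds1 <- simulate_dataset(tiny_config(seed = 10, n_false_positives = 3,
                                      n_echo_duplicates = 3,
                                      n_subdelay_ghosts = 3))
  ds2 <- simulate_dataset(tiny_config(seed = 10, n_false_positives = 3,
                                      n_echo_duplicates = 3,
                                      n_subdelay_ghosts = 3))
  expect_identical(ds1$detections, ds2$detections)
  expect_identical(ds1$truth$detection_labels, ds2$truth$detection_labels)
  expect_identical(ds1$stations, ds2$stations)
})

test_that("noise injection adds exactly the requested labelled records", {
  cfg <- tiny_config(seed = 11, n_false_positives = 10,
                     n_echo_duplicates = 5, n_subdelay_ghosts = 7)
  ds <- simulate_dataset(cfg)
  lab <- ds$truth$detection_labels
  expect_equal(sum(lab$label == "false_positive"), 10)
  expect_equal(sum(lab$label == "duplicate"), 5)
  expect_equal(sum(lab$label == "subdelay_ghost"), 7)
  expect_equal(nrow(lab), nrow(ds$detections))

  # every duplicate matches an existing true row exactly
  dup <- lab[lab$label == "duplicate", c("tag_id", "station_id", "timestamp")]
  true_rows <- lab[lab$label == "true", c("tag_id", "station_id", "timestamp")]
  expect_equal(nrow(dplyr::semi_join(dup, true_rows,
                                     by = c("tag_id", "station_id", "timestamp"))),
               nrow(dup))

  # ghosts sit strictly inside the minimum delay after a same-pair record
  gh <- lab[lab$label == "subdelay_ghost", ]
  ok <- vapply(seq_len(nrow(gh)), function(i) {
    same <- lab$tag_id == gh$tag_id[i] & lab$station_id == gh$station_id[i] &
      lab$label == "true"
    dt <- as.numeric(gh$timestamp[i]) - as.numeric(lab$timestamp[same])
    any(dt > 0 & dt < cfg$min_delay_s)
  }, logical(1))
  expect_true(all(ok))

  # false positives are isolated at their (tag, station) within 24 h
  fp <- lab[lab$label == "false_positive", ]
  iso <- vapply(seq_len(nrow(fp)), function(i) {
    same <- lab$tag_id == fp$tag_id[i] & lab$station_id == fp$station_id[i]
    dt <- abs(as.numeric(lab$timestamp[same]) - as.numeric(fp$timestamp[i]))
    sum(dt <= 86400) == 1  # itself only
  }, logical(1))
  expect_true(all(iso))
})

test_that("generator self-consistency: arrival/departure medians converge", {
  # trajectory-level check at n = 500 fish, tolerance 3 days
  cfg <- simulation_config(seed = 21, n_fish = c(thicklip = 250L, thinlip = 250L),
                           n_years = 1, mortality_fraction = 0)
  fish <- simulate_fish(cfg, simulate_array(cfg))
  tr <- fish$truth$residence
  sp <- fish$truth$fish[, c("fish_id", "species")]
  tr <- dplyr::inner_join(tr, sp, by = "fish_id")
  med_arr <- tapply(doy(tr$true_arrival), tr$species, median)
  med_dep <- tapply(doy(tr$true_departure), tr$species, median)
  expect_lt(abs(med_arr["thicklip"] - 158), 3)
  expect_lt(abs(med_arr["thinlip"] - 135), 3)
  expect_lt(abs(med_dep["thicklip"] - 259), 3)
  expect_lt(abs(med_dep["thinlip"] - 233), 3)
})

test_that("no true detection violates the tag's min delay at a single station", {
  cfg <- tiny_config(seed = 31, n_fish = c(thicklip = 4L, thinlip = 2L),
                     n_years = 1, n_subdelay_ghosts = 8)
  ds <- simulate_dataset(cfg)
  lab <- ds$truth$detection_labels
  true_det <- lab[lab$label == "true", ]
  gaps <- unlist(tapply(as.numeric(true_det$timestamp),
                        paste(true_det$tag_id, true_det$station_id),
                        function(t) diff(sort(t))))
  expect_true(all(gaps == 0 | gaps >= cfg$min_delay_s))
  # and the violations that do exist are exactly the labelled ghosts
  md <- filter_min_delay(ds$detections, ds$deployments)
  expect_equal(md$removed, 8)
})
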