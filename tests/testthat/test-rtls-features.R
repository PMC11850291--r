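test_that("haversine distance matches closed forms and the spherical-law oracle", {
  expect_equal(haversine_distance(10, 20, 10, 20), 0)
  expect_equal(haversine_distance(0, 0, 0, 180), pi * 6371000, tolerance = 1e-9)
  # frozen from an independent spherical-law-of-cosines computation
  expect_equal(haversine_distance(37.2800, 127.0000, 37.2810, 127.0010),
               142.099368377, tolerance = 1e-6)
  # symmetry and range
  expect_equal(haversine_distance(12.3, 45.6, -7.8, 120),
               haversine_distance(-7.8, 120, 12.3, 45.6))
  expect_error(haversine_distance(NA, 0, 0, 0), "finite")
  expect_error(haversine_distance(91, 0, 0, 0), "latitude")
})

test_that("longitude translation leaves small-scale distances invariant", {
  set.seed(4)
  lat <- 37.28 + runif(20, 0, 0.0018)
  lng <- 127 + runif(20, 0, 0.0023)
  d0 <- haversine_distance(lat[-20], lng[-20], lat[-1], lng[-1])
  d1 <- haversine_distance(lat[-20], lng[-20] + 31.7, lat[-1], lng[-1] + 31.7)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("segment_stream produces one segment per consecutive pair", {
  ev1 <- make_events("A", 0, 37.28, 127)
  expect_equal(nrow(segment_stream(ev1)), 0)

  wp <- waypoints_apart(60)
  ev <- make_events("A", c(0, 30), wp$lat, wp$lng)
  seg <- segment_stream(ev)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$dtime, 30)
  expect_equal(seg$velocity, 2.0, tolerance = 1e-6)
  expect_equal(seg$velocity, seg$distance / seg$dtime)
  expect_equal(as.numeric(seg$index_timestamp), as.numeric(ev$timestamp[1]))

  bad <- make_events("A", c(30, 0), wp$lat, wp$lng)
  expect_error(segment_stream(bad), "sorted")

  dup <- make_events("A", c(0, 0, 30), c(wp$lat, wp$lat[1]), c(wp$lng, wp$lng[1]))
  seg2 <- segment_stream(dup)
  expect_equal(attr(seg2, "n_dropped_zero_dtime"), 1L)
  expect_equal(nrow(seg2), 1)
})

test_that("segment velocities match the generator's ground truth on a dwell-free day", {
  wp <- waypoints_apart(100)
  set.seed(8)
  tr <- simulate_trajectory(wp, 1, 5, gait_speed = 0.9, start_time = 0,
                            include_start = TRUE)
  seg <- segment_stream(make_events("A", tr$timestamp, tr$lat, tr$lng))
  expect_equal(seg$velocity, rep(0.9, 5), tolerance = 1e-9)
  d <- daily_metrics(seg)
  expect_equal(d$daily_speed_ms, 0.9, tolerance = 1e-9)
})

test_that("threshold derivation uses linear-interpolation percentiles", {
  th <- derive_thresholds(c(1, 2, 3, 4, 5))
  expect_equal(th$lower20, 1.8)
  expect_equal(th$median, 3)
  expect_equal(th$top20, 4.2)
  expect_warning(derive_thresholds(rep(2, 10)), "degenerate")
  expect_error(derive_thresholds(numeric(0)), "empty")
  def <- velocity_thresholds()
  expect_equal(c(def$top20, def$median, def$lower20), c(1.18, 0.26, 0.02))
  expect_error(velocity_thresholds(0.5, 0.5, 0.5), "lower20 < median < top20")
})

test_that("daily metrics match hand arithmetic and threshold counting", {
  origin <- as.POSIXct("2022-03-01 08:00:00", tz = "UTC")
  seg <- data.frame(patient_id = "A",
                    index_timestamp = origin + c(0, 100),
                    distance = c(100, 20), dtime = c(50, 50),
                    velocity = c(2, 0.4))
  d <- daily_metrics(seg)
  expect_equal(d$total_distance_m, 120)
  expect_equal(d$total_time_s, 100)
  expect_equal(d$daily_speed_ms, 1.2)

  seg2 <- data.frame(patient_id = "A", index_timestamp = origin + c(0, 10, 20),
                     velocity = c(1.5, 0.5, 0.01), dtime = c(10, 10, 10))
  seg2$distance <- seg2$velocity * seg2$dtime
  d2 <- daily_metrics(seg2, velocity_thresholds(1.18, 0.26, 0.02))
  expect_equal(d2$top20_active, 100 / 3, tolerance = 1e-9)
  expect_equal(d2$top50_active, 200 / 3, tolerance = 1e-9)
  expect_equal(d2$not_moving_ratio, 100 / 3, tolerance = 1e-9)

  single <- seg[1, ]
  d3 <- daily_metrics(single)
  expect_equal(d3$velocity_std_ms, 0)
  expect_equal(d3$daily_speed_ms, d3$max_velocity_ms)

  expect_error(daily_metrics(seg[0, ]), "no segments")
  seg_mixed <- seg
  seg_mixed$index_timestamp[2] <- origin + 86400
  expect_error(daily_metrics(seg_mixed), "multiple calendar days")
})

test_that("daily metrics equal a brute-force recomputation from raw coordinates", {
  wp <- ward_waypoints(c(37.28, 37.2818, 127, 127.00226))
  th <- velocity_thresholds()
  set.seed(12)
  for (i in 1:6) {
    tr <- simulate_trajectory(wp, sample(16, 1), sample(3:19, 1), gait_speed = 1.1,
                              start_time = 0, p_active = 0.6,
                              dwell_active_mean = 40, dwell_rest_mean = 800,
                              include_start = TRUE)
    ev <- make_events("Z", tr$timestamp, tr$lat, tr$lng,
                      origin = as.POSIXct("2022-03-05", tz = "UTC"))
    got <- daily_metrics(segment_stream(ev), th)
    want <- daily_metrics_bruteforce(ev, th)
    for (m in names(want))
      expect_equal(got[[m]], want[[m]], tolerance = 1e-9, label = m)
  }
})

test_that("fall censoring keeps strictly pre-fall events and flags empty streams", {
  wp <- waypoints_apart(50)
  ev <- make_events("A", seq(0, 900, by = 100),
                    rep(wp$lat, 5), rep(wp$lng, 5))
  fall <- ev$timestamp[1] + 450
  res <- censor_at_fall(ev, fall)
  expect_equal(nrow(res$events), sum(as.numeric(ev$timestamp) < as.numeric(fall)))
  expect_false(res$flag_exclude)

  res_all <- censor_at_fall(ev, ev$timestamp[10] + 1)
  expect_equal(nrow(res_all$events), 10)

  res_none <- censor_at_fall(ev, ev$timestamp[1] - 1)
  expect_equal(nrow(res_none$events), 0)
  expect_true(res_none$flag_exclude)

  # fall-day mode keeps the whole calendar day
  res_day <- censor_at_fall(ev, fall, mode = "fall_day")
  expect_equal(nrow(res_day$events), 10)
})

test_that("temporal aggregation yields 28 features with correct first/last/mean/median", {
  days <- as.Date("2022-03-01") + 0:2
  dr <- data.frame(patient_id = "A", day = days,
                   total_distance_m = c(10, 20, 90), total_time_s = c(1, 1, 1),
                   daily_speed_ms = c(1, 2, 9), max_velocity_ms = c(1, 2, 9),
                   velocity_std_ms = c(0, 0, 0), top20_active = c(0, 0, 0),
                   top50_active = c(0, 0, 0), not_moving_ratio = c(0, 0, 0))
  row <- aggregate_temporal(dr)
  expect_equal(sum(names(row) %in% rtls_feature_names()), 28)
  expect_equal(row$daily_speed_ms_first, 1)
  expect_equal(row$daily_speed_ms_last, 9)
  expect_equal(row$daily_speed_ms_mean, 4)
  expect_equal(row$daily_speed_ms_median, 2)

  one <- aggregate_temporal(dr[1, ])
  expect_equal(one$daily_speed_ms_first, one$daily_speed_ms_median)
  expect_error(aggregate_temporal(dr[0, ]), "no daily records")
})

test_that("cohort exclusions mirror planted violations", {
  co <- simulate_cohort(tiny_config(n = 10, seed = 21, fall_fraction = 0.3))
  # plant: one patient with a single event, one faller with all events post-fall
  victim <- co$labels$patient_id[co$labels$fall == 0][1]
  co$events <- co$events[!(co$events$patient_id == victim &
                             duplicated(co$events$patient_id)), ]
  faller <- co$labels$patient_id[co$labels$fall == 1][1]
  co$labels$fall_timestamp[co$labels$patient_id == faller] <-
    min(co$events$timestamp[co$events$patient_id == faller]) - 1
  res <- apply_cohort_exclusions(co)
  expect_equal(res$log$n_removed[res$log$rule == "rtls_unavailable"], 1)
  expect_equal(res$log$n_removed[res$log$rule == "no_prefall_rtls"], 1)
  expect_false(victim %in% res$cohort$labels$patient_id)
  expect_false(faller %in% res$cohort$labels$patient_id)

  clean <- simulate_cohort(tiny_config(n = 8, seed = 22))
  res2 <- apply_cohort_exclusions(clean)
  expect_equal(sum(res2$log$n_removed), 0)
})

test_that("cohort-level invariants hold on simulated patient-days", {
  co <- simulate_cohort(simulation_config(n_patients = 150, seed = 55))
  excl <- apply_cohort_exclusions(co)
  seg <- segment_stream(excl$cohort$events)
  daily <- daily_movement_table(seg)
  expect_gt(nrow(daily), 1000)  # at least 1000 patient-days exercised

  # conservation: per-patient daily time sums equal total segment time
  by_seg <- tapply(seg$dtime, seg$patient_id, sum)
  by_day <- tapply(daily$total_time_s, daily$patient_id, sum)
  expect_equal(by_day[names(by_seg)], by_seg, tolerance = 1e-9)

  # ratio ordering and speed bound on every patient-day
  expect_true(all(daily$top20_active <= daily$top50_active + 1e-12))
  expect_true(all(daily$top50_active + daily$not_moving_ratio <= 100 + 1e-12))
  expect_true(all(daily$daily_speed_ms <= daily$max_velocity_ms + 1e-12))
  expect_true(all(daily$top20_active >= 0 & daily$top50_active <= 100 &
                    daily$not_moving_ratio >= 0 & daily$not_moving_ratio <= 100))

  # time-weighting identity: daily speed is the dtime-weighted mean velocity
  wmean <- tapply(seq_len(nrow(seg)), list(seg$patient_id, as.Date(seg$index_timestamp)),
                  function(i) sum(seg$velocity[i] * seg$dtime[i]) / sum(seg$dtime[i]))
  for (i in sample(nrow(daily), 50)) {
    expect_equal(daily$daily_speed_ms[i],
                 wmean[daily$patient_id[i], as.character(daily$day[i])],
                 tolerance = 1e-9)
  }
})

test_that("rtls_features emits exactly 28 features and min <= mean <= max per metric", {
  co <- simulate_cohort(tiny_config(n = 15, seed = 77))
  rt <- rtls_features(co)
  expect_setequal(setdiff(names(rt$features), c("patient_id", "n_days")),
                  rtls_feature_names())
  expect_equal(length(rtls_feature_names()), 28)
  f <- rt$features
  # for each metric, min over days <= mean <= max over days
  seg <- segment_stream(apply_cohort_exclusions(co)$cohort$events)
  daily <- daily_movement_table(seg)
  for (m in c("total_distance_m", "daily_speed_ms", "max_velocity_ms")) {
    lo <- tapply(daily[[m]], daily$patient_id, min)[f$patient_id]
    hi <- tapply(daily[[m]], daily$patient_id, max)[f$patient_id]
    expect_true(all(f[[paste0(m, "_mean")]] >= lo - 1e-12))
    expect_true(all(f[[paste0(m, "_mean")]] <= hi + 1e-12))
  }
  # the aggregate matches the per-patient reference implementation
  pid <- f$patient_id[3]
  ref <- aggregate_temporal(daily[daily$patient_id == pid, ])
  for (nm in rtls_feature_names())
    expect_equal(f[[nm]][f$patient_id == pid], ref[[nm]], tolerance = 1e-12, label = nm)
})
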