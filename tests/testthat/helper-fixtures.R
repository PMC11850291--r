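# Shared fixtures and independent brute-force oracles used across the suite.

# tiny cohort configuration for fast structural tests
tiny_config <- function(n = 20, seed = 101, ...) {
  simulation_config(n_patients = n, seed = seed, los_max = 8, ...)
}

# hand-built event stream: timestamps in seconds offset from a fixed day
make_events <- function(patient_id, offsets, lats, lngs,
                        origin = as.POSIXct("2022-03-01", tz = "UTC")) {
  data.frame(patient_id = patient_id,
             timestamp = origin + offsets, lat = lats, lng = lngs,
             stringsAsFactors = FALSE)
}

# two waypoints exactly `metres` apart along a meridian (pure latitude shift)
waypoints_apart <- function(metres, lat0 = 37.28, lng0 = 127) {
  dlat <- metres / (pi / 180 * 6371000)
  data.frame(name = c("A", "B"), lat = c(lat0, lat0 + dlat), lng = c(lng0, lng0),
             stringsAsFactors = FALSE)
}

# O(n^2) concordance-counting AUROC oracle
auroc_bruteforce <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force net benefit from an explicit confusion matrix
net_benefit_bruteforce <- function(labels, probs, t) {
  calls <- as.integer(probs >= t)
  tp <- sum(calls == 1 & labels == 1)
  fp <- sum(calls == 1 & labels == 0)
  tp / length(labels) - fp / length(labels) * t / (1 - t)
}

# brute-force daily metrics recomputed from raw coordinates of one patient-day
daily_metrics_bruteforce <- function(events, thresholds) {
  n <- nrow(events)
  d <- dt <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    d[i] <- haversine_distance(events$lat[i], events$lng[i],
                               events$lat[i + 1], events$lng[i + 1])
    dt[i] <- as.numeric(events$timestamp[i + 1]) - as.numeric(events$timestamp[i])
  }
  v <- d / dt
  list(total_distance_m = sum(d),
       total_time_s = sum(dt),
       daily_speed_ms = sum(d) / sum(dt),
       max_velocity_ms = max(v),
       velocity_std_ms = sqrt(sum((v - mean(v))^2) / length(v)),
       top20_active = 100 * sum(dt[v >= thresholds$top20]) / sum(dt),
       top50_active = 100 * sum(dt[v >= thresholds$median]) / sum(dt),
       not_moving_ratio = 100 * sum(dt[v <= thresholds$lower20]) / sum(dt))
}

# feature tables + labels for modelling tests, one call per seed
cohort_model_inputs <- function(cfg) {
  co <- simulate_cohort(cfg)
  rt <- rtls_features(co)
  cl <- clinical_features(list(emr = co$emr[co$emr$patient_id %in% rt$labels$patient_id, ]))
  ids <- rt$labels$patient_id
  rx <- rt$features[match(ids, rt$features$patient_id),
                    c("patient_id", rtls_feature_names())]
  cx <- cl$features[match(ids, cl$features$patient_id), ]
  list(clinical = cx, rtls = rx,
       combined = cbind(cx, rx[, rtls_feature_names()]),
       y = rt$labels$fall, cohort = co, rt = rt)
}
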