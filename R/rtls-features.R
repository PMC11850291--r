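# Movement feature engineering from event-triggered RTLS streams:
# segment physics, daily movement metrics, velocity-threshold activity
# ratios and first/last/mean/median temporal aggregation.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of the given radius (default: mean earth
#' radius, 6371 km). Vectorised over all arguments.
#'
#' @param lat1,lng1,lat2,lng2 coordinates in decimal degrees.
#' @param radius sphere radius in meters.
#' @return distance in meters.
#' @export
haversine_distance <- function(lat1, lng1, lat2, lng2, radius = EARTH_RADIUS_M) {
  if (any(!is.finite(c(lat1, lng1, lat2, lng2))) || !is.finite(radius) || radius <= 0)
    stop("haversine_distance: coordinates and radius must be finite (radius > 0)")
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90) ||
      any(abs(lng1) > 180) || any(abs(lng2) > 180))
    stop("haversine_distance: latitude must be in [-90, 90], longitude in [-180, 180]")
  geosphere::distHaversine(cbind(lng1, lat1), cbind(lng2, lat2), r = radius)
}

#' Reference velocity thresholds for the activity ratios
#'
#' The three operating thresholds separating active from resting movement:
#' the top-20% velocity (default 1.18 m/s, normal adult walking speed), the
#' median velocity (0.26 m/s) and the lower-20% velocity (0.02 m/s, minimal
#' movement). The fixed defaults are the recommended operating mode so that
#' features do not drift with cohort composition; [derive_thresholds()]
#' recomputes them from a velocity pool instead.
#'
#' @param top20,median,lower20 thresholds in m/s, strictly ordered
#'   `lower20 < median < top20`.
#' @return object of class `velocity_thresholds`.
#' @export
velocity_thresholds <- function(top20 = 1.18, median = 0.26, lower20 = 0.02) {
  stopifnot(is.finite(top20), is.finite(median), is.finite(lower20))
  if (!(lower20 < median && median < top20))
    stop("velocity thresholds must satisfy lower20 < median < top20")
  structure(list(top20 = top20, median = median, lower20 = lower20),
            class = "velocity_thresholds")
}

#' Derive velocity thresholds from a pooled velocity distribution
#'
#' Computes the 80th, 50th and 20th percentiles (linear interpolation between
#' order statistics) of all segment velocities pooled over a cohort.
#'
#' @param velocities numeric vector of segment velocities (m/s), length >= 5.
#' @return object of class `velocity_thresholds`. If the pool is degenerate
#'   (percentiles not strictly ordered) a warning is raised and the
#'   unvalidated thresholds are returned.
#' @export
derive_thresholds <- function(velocities) {
  velocities <- velocities[is.finite(velocities)]
  if (length(velocities) == 0L) stop("cannot derive thresholds from an empty velocity pool")
  if (length(velocities) < 5L) stop("need at least 5 velocities to derive thresholds")
  q <- quantile(velocities, c(0.8, 0.5, 0.2), names = FALSE, type = 7)
  if (!(q[3] < q[2] && q[2] < q[1])) {
    warning("degenerate velocity pool: derived thresholds are not strictly ordered")
    return(structure(list(top20 = q[1], median = q[2], lower20 = q[3]),
                     class = "velocity_thresholds"))
  }
  velocity_thresholds(top20 = q[1], median = q[2], lower20 = q[3])
}

#' Movement segments from an event stream
#'
#' Turns consecutive location events into movement segments carrying the
#' great-circle distance (m), elapsed time (s) and velocity (m/s) of each
#' consecutive event pair. Each segment is indexed by the earlier timestamp
#' of its pair (the reference point for day assignment). Segments with zero
#' elapsed time (duplicate clock readings) are dropped, with the count
#' recorded in the `n_dropped_zero_dtime` attribute, because their velocity
#' is undefined.
#'
#' @param events data.frame with `patient_id`, `timestamp` (POSIXct or
#'   numeric), `lat`, `lng`; one or several patients, sorted by timestamp
#'   within patient.
#' @return data.frame with `patient_id`, `index_timestamp`, `distance`,
#'   `dtime`, `velocity`; fewer than 2 events for a patient yield no rows.
#' @export
segment_stream <- function(events) {
  need <- c("patient_id", "timestamp", "lat", "lng")
  if (!all(need %in% names(events)))
    stop("events must have columns patient_id, timestamp, lat, lng")
  out <- data.frame(patient_id = character(0), index_timestamp = as_utc(numeric(0)),
                    distance = numeric(0), dtime = numeric(0), velocity = numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_zero_dtime") <- 0L
  if (nrow(events) < 2L) return(out)
  dt <- as.data.table(events)
  dt[, timestamp := as.numeric(timestamp)]
  seg <- dt[, if (.N >= 2L) {
    if (is.unsorted(timestamp)) stop("events must be sorted by timestamp within patient")
    .(index_timestamp = timestamp[-.N],
      distance = haversine_distance(lat[-.N], lng[-.N], lat[-1L], lng[-1L]),
      dtime = diff(timestamp))
  }, by = patient_id]
  if (nrow(seg) == 0L) return(out)
  dropped <- sum(seg$dtime == 0)
  seg <- seg[dtime > 0]
  seg[, velocity := distance / dtime]
  seg <- as.data.frame(seg)
  seg$index_timestamp <- as_utc(seg$index_timestamp)
  attr(seg, "n_dropped_zero_dtime") <- dropped
  seg
}

.metric_names <- c("total_distance_m", "daily_speed_ms", "max_velocity_ms",
                   "velocity_std_ms", "top20_active", "top50_active",
                   "not_moving_ratio")

#' Names of the 28 aggregated RTLS features
#' @return character vector: each of the 7 daily metrics crossed with
#'   first/last/mean/median.
#' @export
rtls_feature_names <- function() {
  as.vector(t(outer(.metric_names, c("first", "last", "mean", "median"), paste, sep = "_")))
}

.daily_from_segments <- function(seg_dt, thresholds) {
  seg_dt[, .(
    total_distance_m = sum(distance),
    total_time_s = sum(dtime),
    daily_speed_ms = sum(distance) / sum(dtime),
    max_velocity_ms = max(velocity),
    velocity_std_ms = sqrt(mean((velocity - mean(velocity))^2)),
    top20_active = 100 * sum(dtime[velocity >= thresholds$top20]) / sum(dtime),
    top50_active = 100 * sum(dtime[velocity >= thresholds$median]) / sum(dtime),
    not_moving_ratio = 100 * sum(dtime[velocity <= thresholds$lower20]) / sum(dtime),
    n_segments = .N
  ), by = .(patient_id, day)]
}

#' Daily movement metrics for one patient-day
#'
#' Aggregates the segments of a single patient-day into the seven daily
#' metrics: total distance (m), total estimated time (s), daily speed
#' (distance/time, the time-weighted mean velocity), maximum velocity,
#' population standard deviation of segment velocities, and the three
#' threshold activity ratios (percent of tracked time spent at or above the
#' top-20% and median velocity thresholds, and at or below the lower-20%
#' threshold).
#'
#' @param segments segment rows for one patient-day (see [segment_stream()]).
#' @param thresholds a [velocity_thresholds()] object.
#' @return one-row data.frame with the daily metrics plus `total_time_s` and
#'   `n_segments`.
#' @export
daily_metrics <- function(segments, thresholds = velocity_thresholds()) {
  if (nrow(segments) == 0L) stop("daily_metrics: no segments supplied")
  day <- unique(utc_date(segments$index_timestamp))
  if (length(day) != 1L) stop("daily_metrics: segments span multiple calendar days")
  if (length(unique(segments$patient_id)) != 1L)
    stop("daily_metrics: segments span multiple patients")
  dt <- as.data.table(segments)
  dt[, day := utc_date(index_timestamp)]
  as.data.frame(.daily_from_segments(dt, thresholds))
}

#' Daily movement metrics for a whole cohort
#'
#' Vectorised version of [daily_metrics()]: assigns every segment to the
#' calendar day (UTC) of its index timestamp and computes the daily metrics
#' per patient-day.
#'
#' @param segments segment table from [segment_stream()].
#' @param thresholds a [velocity_thresholds()] object.
#' @return data.frame keyed by `patient_id`, `day`.
#' @export
daily_movement_table <- function(segments, thresholds = velocity_thresholds()) {
  dt <- as.data.table(segments)
  if (nrow(dt) == 0L)
    return(data.frame(patient_id = character(0), day = as.Date(character(0))))
  dt[, day := utc_date(index_timestamp)]
  out <- .daily_from_segments(dt, thresholds)
  data.table::setorder(out, patient_id, day)
  as.data.frame(out)
}

#' Censor a faller's event stream at the fall
#'
#' @param events events of one patient, sorted by timestamp.
#' @param fall_timestamp fall instant (POSIXct or numeric); `NA` leaves the
#'   stream untouched.
#' @param mode `"strict"` keeps only events strictly before the fall;
#'   `"fall_day"` keeps every event up to the end of the fall's calendar day.
#' @return list with `events` (censored stream) and `flag_exclude` (`TRUE`
#'   when fewer than 2 pre-fall events remain, i.e. no movement features can
#'   be engineered).
#' @export
censor_at_fall <- function(events, fall_timestamp, mode = c("strict", "fall_day")) {
  mode <- match.arg(mode)
  if (is.na(fall_timestamp))
    return(list(events = events, flag_exclude = nrow(events) < 2L))
  cutoff <- if (mode == "strict") as.numeric(fall_timestamp)
    else as.numeric(as.POSIXct(utc_date(fall_timestamp) + 1L, tz = "UTC"))
  kept <- events[as.numeric(events$timestamp) < cutoff, , drop = FALSE]
  list(events = kept, flag_exclude = nrow(kept) < 2L)
}

#' Aggregate a patient's daily metrics into the 28 RTLS features
#'
#' For each of the seven daily metrics, takes the value on the first and the
#' last day with recorded movement, and the mean and median over all recorded
#' days. Days without segments contribute nothing (they are skipped, not
#' zero-filled).
#'
#' @param daily_records daily metric rows of one patient
#'   (see [daily_movement_table()]).
#' @return one-row data.frame with `patient_id`, `n_days` and the 28 features
#'   named as in [rtls_feature_names()].
#' @export
aggregate_temporal <- function(daily_records) {
  if (nrow(daily_records) == 0L)
    stop("aggregate_temporal: patient has no daily records (exclude upstream)")
  if (length(unique(daily_records$patient_id)) != 1L)
    stop("aggregate_temporal: records span multiple patients")
  dr <- daily_records[order(daily_records$day), , drop = FALSE]
  out <- list(patient_id = dr$patient_id[1], n_days = nrow(dr))
  for (m in .metric_names) {
    v <- dr[[m]]
    out[[paste0(m, "_first")]] <- v[1]
    out[[paste0(m, "_last")]] <- v[length(v)]
    out[[paste0(m, "_mean")]] <- mean(v)
    out[[paste0(m, "_median")]] <- median(v)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Apply the cohort RTLS-completeness exclusions
#'
#' Mirrors the cohort-refinement flowchart: patients whose location stream is
#' unusable (fewer than 2 events over the whole stay) are removed, and
#' fallers with fewer than 2 events before the fall (no pre-fall movement
#' recorded) are removed. Returns the filtered cohort plus a per-rule count
#' log.
#'
#' @param cohort a `fall_cohort` (or any list with `events` and `labels`).
#' @param censor_mode passed to [censor_at_fall()] for the pre-fall check.
#' @return list with `cohort` (filtered, events of fallers censored) and
#'   `log` (data.frame `rule`, `n_removed`, `n_remaining`).
#' @export
apply_cohort_exclusions <- function(cohort, censor_mode = c("strict", "fall_day")) {
  censor_mode <- match.arg(censor_mode)
  labels <- cohort$labels
  ev <- as.data.table(cohort$events)
  n0 <- nrow(labels)
  counts <- if (nrow(ev)) ev[, .(n_events = .N), by = patient_id]
    else data.table(patient_id = character(0), n_events = integer(0))
  nev <- counts$n_events[match(labels$patient_id, counts$patient_id)]
  nev[is.na(nev)] <- 0L
  usable <- nev >= 2L
  log <- data.frame(rule = "rtls_unavailable", n_removed = sum(!usable),
                    n_remaining = sum(usable), stringsAsFactors = FALSE)
  labels <- labels[usable, , drop = FALSE]

  # censor fallers (vectorised) and flag those with no pre-fall movement
  ev <- ev[patient_id %in% labels$patient_id]
  cutoff <- rep(Inf, nrow(labels))
  faller <- labels$fall == 1L & !is.na(labels$fall_timestamp)
  cutoff[faller] <- if (censor_mode == "strict") {
    as.numeric(labels$fall_timestamp[faller])
  } else {
    as.numeric(as.POSIXct(utc_date(labels$fall_timestamp[faller]) + 1L, tz = "UTC"))
  }
  ev[, `:=`(cut = cutoff[match(patient_id, labels$patient_id)])]
  ev <- ev[as.numeric(timestamp) < cut][, cut := NULL]
  counts <- ev[, .(n_events = .N), by = patient_id]
  nev <- counts$n_events[match(labels$patient_id, counts$patient_id)]
  nev[is.na(nev)] <- 0L
  keep <- nev >= 2L
  log <- rbind(log, data.frame(rule = "no_prefall_rtls", n_removed = sum(!keep),
                               n_remaining = sum(keep)))
  labels <- labels[keep, , drop = FALSE]
  events <- as.data.frame(ev[patient_id %in% labels$patient_id])
  rownames(events) <- NULL
  out <- cohort
  out$events <- events
  out$labels <- labels
  if (!is.null(out$emr))
    out$emr <- out$emr[out$emr$patient_id %in% labels$patient_id, , drop = FALSE]
  list(cohort = out, log = log)
}

#' Engineer the 28-feature RTLS table for a cohort
#'
#' Full movement feature pipeline: censor fallers at the fall, apply the
#' RTLS-completeness exclusions, segment every stream, compute daily metrics
#' and aggregate them into the 28 per-patient features.
#'
#' @param cohort a `fall_cohort`.
#' @param thresholds a [velocity_thresholds()] object (fixed defaults unless
#'   `derive = TRUE`).
#' @param derive derive thresholds from this cohort's pooled velocities
#'   instead of using the fixed operating thresholds.
#' @param censor_mode fall censoring mode, see [censor_at_fall()].
#' @return list with `features` (data.frame: `patient_id`, `n_days`, 28
#'   features), `labels` (rows for retained patients), `exclusions` (count
#'   log), `thresholds`, and `n_dropped_zero_dtime`.
#' @export
rtls_features <- function(cohort, thresholds = velocity_thresholds(),
                          derive = FALSE, censor_mode = c("strict", "fall_day")) {
  censor_mode <- match.arg(censor_mode)
  excl <- apply_cohort_exclusions(cohort, censor_mode = censor_mode)
  seg <- segment_stream(excl$cohort$events)
  if (derive) thresholds <- derive_thresholds(seg$velocity)
  daily <- daily_movement_table(seg, thresholds)
  dt <- as.data.table(daily)
  mn <- .metric_names
  feats <- dt[, {
    dr <- .SD[order(day)]
    res <- list(n_days = .N)
    for (m in mn) {
      v <- dr[[m]]
      res[[paste0(m, "_first")]] <- v[1L]
      res[[paste0(m, "_last")]] <- v[.N]
      res[[paste0(m, "_mean")]] <- mean(v)
      res[[paste0(m, "_median")]] <- median(v)
    }
    res
  }, by = patient_id]
  feats <- as.data.frame(feats)
  feats <- feats[match(excl$cohort$labels$patient_id, feats$patient_id), , drop = FALSE]
  rownames(feats) <- NULL
  list(features = feats, labels = excl$cohort$labels, exclusions = excl$log,
       thresholds = thresholds,
       n_dropped_zero_dtime = attr(seg, "n_dropped_zero_dtime"))
}
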