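# Synthetic inpatient cohort generator: event-triggered RTLS streams plus an
# EMR-style clinical table with configurable fall/non-fall group contrasts.

#' Default clinical group contrasts between fallers and non-fallers
#'
#' Returns the per-covariate contrasts applied to the faller group by
#' [simulate_cohort()]. Defaults reproduce the direction and magnitude of the
#' published baseline-table differences between inpatients who fell and those
#' who did not: more males, older, longer stay, more sedative/antipsychotic
#' exposure, higher pulse rate and red cell distribution width (RDW), lower
#' BMI, more ICU admissions and a shift toward medical (vs. surgical)
#' departments. Pass `NULL` as `clinical_effects` to generate a cohort with no
#' clinical signal at all.
#'
#' @param male_shift additive shift on the faller male probability.
#' @param age_shift additive shift (years) on faller mean age.
#' @param los_factor multiplicative factor on the faller length-of-stay
#'   distribution median (faller LOS runs admission to fall day).
#' @param icu_prob,sedative_prob,peridol_prob faller exposure probabilities
#'   (non-faller baselines live in the generator schema).
#' @param dept_probs faller department category probabilities; named vector
#'   over `medicine`, `major_surgery`, `minor_surgery`, `others`.
#' @param lab_shifts named additive shifts (faller minus non-faller) on the
#'   continuous vitals and laboratory means, in each variable's native unit.
#' @return A list of contrasts understood by [simulate_cohort()].
#' @export
fall_contrasts <- function(male_shift = 0.161,
                           age_shift = 3.5,
                           los_factor = 1.5,
                           icu_prob = 0.110,
                           sedative_prob = 0.432,
                           peridol_prob = 0.127,
                           dept_probs = c(medicine = 0.686, major_surgery = 0.246,
                                          minor_surgery = 0.059, others = 0.009),
                           lab_shifts = c(sbp = 0.2, dbp = 0, pulse_rate = 4.2,
                                          bmi = -0.8, albumin = -0.1, alp = 1.6,
                                          alt = -9.5, ast = -4.7,
                                          total_bilirubin = 0, bun = 1.7,
                                          calcium = 0, total_cholesterol = -6.4,
                                          creatinine = 0.3, glucose = 10.3,
                                          hct = -1.4, haemoglobin = -0.4,
                                          phosphate = -0.2, total_protein = 0,
                                          rdw = 0.9, uric_acid = 0.2)) {
  list(male_shift = male_shift, age_shift = age_shift, los_factor = los_factor,
       icu_prob = icu_prob, sedative_prob = sedative_prob,
       peridol_prob = peridol_prob, dept_probs = dept_probs,
       lab_shifts = lab_shifts)
}

#' Default ward waypoint set
#'
#' A regular grid of named waypoints inside a bounding box, standing in for
#' beds, bathrooms and corridor positions of a ward.
#'
#' @param ward_bounds numeric vector `c(lat_min, lat_max, lng_min, lng_max)`
#'   in decimal degrees.
#' @param n_side grid points per side (`n_side^2` waypoints).
#' @return data.frame with columns `name`, `lat`, `lng`.
#' @export
ward_waypoints <- function(ward_bounds, n_side = 4L) {
  lat <- seq(ward_bounds[1], ward_bounds[2], length.out = n_side + 2L)[-c(1L, n_side + 2L)]
  lng <- seq(ward_bounds[3], ward_bounds[4], length.out = n_side + 2L)[-c(1L, n_side + 2L)]
  g <- expand.grid(lat = lat, lng = lng, KEEP.OUT.ATTRS = FALSE)
  data.frame(name = sprintf("W%02d", seq_len(nrow(g))), lat = g$lat, lng = g$lng,
             stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic inpatient cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults are
#' the package's reference study conditions: a ~200 m x 200 m ward at latitude
#' 37.28 deg, ~60 waypoint-to-waypoint trips per patient-day giving a median
#' daily total distance around 4.6 km, a length-of-stay distribution with
#' median ~5 days (IQR ~3-11), a ~21% faller fraction, and faller movement
#' declines concentrated on the final `ramp_days` days before the fall
#' (slower gait, proportionally longer dwells, fewer trips) with a trip-count
#' inflation on the fall day itself.
#'
#' @param n_patients number of patients.
#' @param fall_fraction proportion of patients labelled as fallers, in
#'   `[0, 1]`.
#' @param los_meanlog,los_sdlog,los_max log-normal length-of-stay parameters
#'   (days; rounded to an integer of at least 1, capped at `los_max`).
#' @param ward_bounds `c(lat_min, lat_max, lng_min, lng_max)` degrees.
#' @param waypoints data.frame of named coordinates inside `ward_bounds`
#'   (columns `name`, `lat`, `lng`); defaults to [ward_waypoints()].
#' @param trips_per_day Poisson mean of the daily trip count for a patient of
#'   average activity.
#' @param p_active probability that a dwell preceding a trip is a short
#'   "active-period" dwell rather than a long rest.
#' @param dwell_active_mean,dwell_rest_mean exponential means (seconds) of the
#'   two dwell classes.
#' @param base_gait_speed,gait_speed_sd mean and between-patient SD of gait
#'   speed (m/s) while actually walking.
#' @param activity_sdlog between-patient log-normal SD of the activity
#'   multiplier scaling the daily trip count.
#' @param day_speed_sdlog,day_trips_sdlog day-level log-normal SDs of the
#'   multipliers on gait pace (with reciprocal dwell scaling) and on the
#'   daily trip count: day-to-day fluctuation of a patient's condition.
#' @param frailty_weight strength of the shared latent frailty factor that
#'   correlates the clinical covariates within groups (sicker patients have
#'   jointly higher RDW and pulse, more sedative use, longer stays, lower
#'   BMI); 0 draws covariates independently. Group contrasts are unchanged;
#'   only the within-group covariance grows.
#' @param faller_speed_decline multiplicative factor (< 1) on faller gait
#'   speed at the fall day; dwell times are inflated by its reciprocal so the
#'   whole day slows down, not just the walking legs.
#' @param faller_activity_decline multiplicative factor (< 1) on the faller
#'   daily trip count at the fall day.
#' @param faller_distance_inflation multiplicative factor (>= 1) on the faller
#'   fall-day trip count, emulating restless extra movement despite slower,
#'   less active motion.
#' @param ramp_days movement declines are interpolated linearly from no effect
#'   `ramp_days` before the fall to full effect on the fall day.
#' @param post_fall_days days of events still generated after the fall
#'   (censoring them is the feature engine's job).
#' @param day_start_hour hour of day at which daily activity begins.
#' @param clinical_effects list from [fall_contrasts()], or `NULL` for no
#'   clinical group contrasts.
#' @param missingness_rate proportion of eligible vital/lab cells blanked, in
#'   `[0, 1)`.
#' @param seed integer RNG seed; the whole cohort is a deterministic function
#'   of the configuration including the seed.
#' @return A validated list of class `fall_sim_config`.
#' @export
simulation_config <- function(n_patients = 600L,
                              fall_fraction = 0.21,
                              los_meanlog = log(5),
                              los_sdlog = 1.17,
                              los_max = 30L,
                              ward_bounds = c(37.2800, 37.2818, 127.0000, 127.00226),
                              waypoints = NULL,
                              trips_per_day = 60,
                              p_active = 0.6,
                              dwell_active_mean = 60,
                              dwell_rest_mean = 2000,
                              base_gait_speed = 1.3,
                              gait_speed_sd = 0.15,
                              activity_sdlog = 0.45,
                              day_speed_sdlog = 0.25,
                              day_trips_sdlog = 0.35,
                              frailty_weight = 0.5,
                              faller_speed_decline = 0.65,
                              faller_activity_decline = 0.75,
                              faller_distance_inflation = 1.25,
                              ramp_days = 3L,
                              post_fall_days = 1L,
                              day_start_hour = 7,
                              clinical_effects = fall_contrasts(),
                              missingness_rate = 0.05,
                              seed = 1L) {
  check_number(n_patients, "n_patients", lower = 0)
  check_number(fall_fraction, "fall_fraction", 0, 1)
  check_number(los_meanlog, "los_meanlog")
  check_number(los_sdlog, "los_sdlog", lower = 0)
  check_number(los_max, "los_max", lower = 1)
  if (!is.numeric(ward_bounds) || length(ward_bounds) != 4L || any(!is.finite(ward_bounds)))
    stop_bad_field("ward_bounds", "must be c(lat_min, lat_max, lng_min, lng_max)")
  if (ward_bounds[1] >= ward_bounds[2] || ward_bounds[3] >= ward_bounds[4])
    stop_bad_field("ward_bounds", "bounds must be strictly ordered")
  if (is.null(waypoints)) waypoints <- ward_waypoints(ward_bounds)
  if (!all(c("name", "lat", "lng") %in% names(waypoints)) || nrow(waypoints) < 1L)
    stop_bad_field("waypoints", "need columns name/lat/lng and at least one row")
  inside <- waypoints$lat >= ward_bounds[1] & waypoints$lat <= ward_bounds[2] &
    waypoints$lng >= ward_bounds[3] & waypoints$lng <= ward_bounds[4]
  if (!all(inside))
    stop_bad_field("waypoints", "all waypoints must lie inside ward_bounds")
  check_number(trips_per_day, "trips_per_day", lower = 0)
  check_number(p_active, "p_active", 0, 1)
  check_number(dwell_active_mean, "dwell_active_mean", lower = 0)
  check_number(dwell_rest_mean, "dwell_rest_mean", lower = 0)
  check_number(base_gait_speed, "base_gait_speed", lower = 0, allow_lower = FALSE)
  check_number(gait_speed_sd, "gait_speed_sd", lower = 0)
  check_number(activity_sdlog, "activity_sdlog", lower = 0)
  check_number(day_speed_sdlog, "day_speed_sdlog", lower = 0)
  check_number(day_trips_sdlog, "day_trips_sdlog", lower = 0)
  check_number(frailty_weight, "frailty_weight", lower = 0)
  check_number(faller_speed_decline, "faller_speed_decline", lower = 0, allow_lower = FALSE)
  check_number(faller_activity_decline, "faller_activity_decline", lower = 0, allow_lower = FALSE)
  check_number(faller_distance_inflation, "faller_distance_inflation", lower = 0, allow_lower = FALSE)
  check_number(ramp_days, "ramp_days", lower = 1)
  check_number(post_fall_days, "post_fall_days", lower = 0)
  check_number(day_start_hour, "day_start_hour", 0, 20)
  check_number(missingness_rate, "missingness_rate", 0, 1, allow_upper = FALSE)
  check_number(seed, "seed")
  structure(list(
    n_patients = as.integer(n_patients), fall_fraction = fall_fraction,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog, los_max = as.integer(los_max),
    ward_bounds = ward_bounds, waypoints = waypoints,
    trips_per_day = trips_per_day, p_active = p_active,
    dwell_active_mean = dwell_active_mean, dwell_rest_mean = dwell_rest_mean,
    base_gait_speed = base_gait_speed, gait_speed_sd = gait_speed_sd,
    activity_sdlog = activity_sdlog, day_speed_sdlog = day_speed_sdlog,
    day_trips_sdlog = day_trips_sdlog, frailty_weight = frailty_weight,
    faller_speed_decline = faller_speed_decline,
    faller_activity_decline = faller_activity_decline,
    faller_distance_inflation = faller_distance_inflation,
    ramp_days = as.integer(ramp_days), post_fall_days = as.integer(post_fall_days),
    day_start_hour = day_start_hour, clinical_effects = clinical_effects,
    missingness_rate = missingness_rate, seed = as.integer(seed)
  ), class = "fall_sim_config")
}

#' Simulate one day of event-triggered movement
#'
#' Generates the RTLS event stream of a single patient-day under the
#' waypoint-hopping movement model: the patient dwells at a waypoint, then
#' walks in a straight (great-circle) line to a different waypoint at their
#' gait speed; the location system emits an event only on arrival at the new
#' waypoint. Trips whose arrival would exceed `max_time` are not taken.
#'
#' @param waypoints data.frame with `name`, `lat`, `lng`.
#' @param start_index index of the waypoint the patient occupies at
#'   `start_time`.
#' @param n_trips number of waypoint changes attempted.
#' @param gait_speed walking speed, m/s (> 0).
#' @param start_time numeric or POSIXct start of the day's activity.
#' @param p_active,dwell_active_mean,dwell_rest_mean dwell mixture parameters
#'   (seconds); a mean of 0 gives zero dwell.
#' @param dwell_scale multiplicative factor on all dwell times.
#' @param max_time events after this time are not generated (`Inf` to disable).
#' @param include_start emit an event for the starting position (used for the
#'   admission record); subsequent days chain from the previous position and
#'   must not re-emit it, since the system only logs location changes.
#' @return data.frame with `timestamp` (numeric seconds), `lat`, `lng`,
#'   `waypoint`, plus attribute `end_index` (waypoint occupied at day end).
#' @export
simulate_trajectory <- function(waypoints, start_index, n_trips, gait_speed,
                                start_time,
                                p_active = 1, dwell_active_mean = 0,
                                dwell_rest_mean = 0, dwell_scale = 1,
                                max_time = Inf, include_start = FALSE) {
  k <- nrow(waypoints)
  dmat <- .waypoint_distances(waypoints)
  day <- .sim_day(k, dmat, start_index, n_trips, gait_speed, as.numeric(start_time),
                  p_active, dwell_active_mean, dwell_rest_mean, dwell_scale,
                  max_time, include_start)
  out <- data.frame(timestamp = day$timestamp, lat = waypoints$lat[day$wp],
                    lng = waypoints$lng[day$wp], waypoint = waypoints$name[day$wp],
                    stringsAsFactors = FALSE)
  attr(out, "end_index") <- day$end_index
  out
}

.waypoint_distances <- function(waypoints) {
  k <- nrow(waypoints)
  i <- rep(seq_len(k), each = k); j <- rep(seq_len(k), k)
  matrix(haversine_distance(waypoints$lat[i], waypoints$lng[i],
                            waypoints$lat[j], waypoints$lng[j]), k, k)
}

# movement kernel for one patient-day; returns plain vectors for speed
.sim_day <- function(k, dmat, start_index, n_trips, gait_speed, t0,
                     p_active, dwell_active_mean, dwell_rest_mean,
                     dwell_scale, max_time, include_start) {
  stopifnot(is.finite(gait_speed), gait_speed > 0, n_trips >= 0)
  if (k < 2L && n_trips > 0L)
    stop("cannot move with a single waypoint: no location change is possible")
  ts0 <- if (include_start) t0 else numeric(0)
  wp0 <- if (include_start) start_index else integer(0)
  if (n_trips == 0L)
    return(list(timestamp = ts0, wp = wp0, end_index = start_index))
  # waypoint chain: adding a step in 1..(k-1) modulo k never repeats a position
  steps <- sample.int(k - 1L, n_trips, replace = TRUE)
  wp <- ((start_index - 1L + cumsum(steps)) %% k) + 1L
  from <- c(start_index, wp[-n_trips])
  dist <- dmat[cbind(from, wp)]
  draw_dwell <- function(n, mean) if (mean <= 0) rep(0, n) else rexp(n, rate = 1 / mean)
  active <- runif(n_trips) < p_active
  dwell <- ifelse(active, draw_dwell(n_trips, dwell_active_mean),
                  draw_dwell(n_trips, dwell_rest_mean)) * dwell_scale
  arrival <- t0 + cumsum(dwell + dist / gait_speed)
  keep <- arrival <= max_time          # prefix of the chain: continuity preserved
  wp <- wp[keep]; arrival <- arrival[keep]
  list(timestamp = c(ts0, arrival), wp = c(wp0, wp),
       end_index = if (length(wp)) wp[length(wp)] else start_index)
}

# continuous vitals/labs schema: generating distribution per variable, tuned
# to the non-faller group of the reference baseline table
.lab_schema <- function() {
  rbind(
    data.frame(var = "sbp", dist = "normal", mean = 128.5, sd = 21.0, min = 60),
    data.frame(var = "dbp", dist = "normal", mean = 77.2, sd = 13.9, min = 35),
    data.frame(var = "pulse_rate", dist = "normal", mean = 74.8, sd = 15.6, min = 35),
    data.frame(var = "bmi", dist = "normal", mean = 23.8, sd = 3.8, min = 12),
    data.frame(var = "albumin", dist = "normal", mean = 3.9, sd = 0.7, min = 1.2),
    data.frame(var = "alp", dist = "lognormal", mean = 97.1, sd = 90.2, min = 5),
    data.frame(var = "alt", dist = "lognormal", mean = 34.1, sd = 85.7, min = 2),
    data.frame(var = "ast", dist = "lognormal", mean = 41.8, sd = 66.7, min = 4),
    data.frame(var = "total_bilirubin", dist = "lognormal", mean = 0.9, sd = 1.6, min = 0.1),
    data.frame(var = "bun", dist = "lognormal", mean = 21.7, sd = 17.9, min = 2),
    data.frame(var = "calcium", dist = "normal", mean = 8.7, sd = 0.6, min = 5.5),
    data.frame(var = "total_cholesterol", dist = "normal", mean = 152.2, sd = 46.1, min = 40),
    data.frame(var = "creatinine", dist = "lognormal", mean = 1.2, sd = 1.7, min = 0.2),
    data.frame(var = "glucose", dist = "lognormal", mean = 138.9, sd = 73.1, min = 40),
    data.frame(var = "hct", dist = "normal", mean = 36.9, sd = 6.8, min = 12),
    data.frame(var = "haemoglobin", dist = "normal", mean = 12.3, sd = 2.4, min = 4),
    data.frame(var = "phosphate", dist = "normal", mean = 3.5, sd = 1.1, min = 0.8),
    data.frame(var = "total_protein", dist = "normal", mean = 6.4, sd = 0.8, min = 3.5),
    data.frame(var = "rdw", dist = "normal", mean = 13.5, sd = 2.2, min = 10.5),
    data.frame(var = "uric_acid", dist = "normal", mean = 5.0, sd = 2.2, min = 0.8)
  )
}

#' Column names of the clinical feature schema
#' @return character vector of the 27 clinical variables (excluding
#'   `patient_id`).
#' @export
clinical_schema <- function() {
  c("sex", "age", "los", "department", "icu", "sbp", "dbp", "pulse_rate",
    "bmi", "sedative", "peridol", "albumin", "alp", "alt", "ast",
    "total_bilirubin", "bun", "calcium", "total_cholesterol", "creatinine",
    "glucose", "hct", "haemoglobin", "phosphate", "total_protein", "rdw",
    "uric_acid")
}

.gen_continuous <- function(n, dist, mean, sd, min) {
  x <- if (dist == "lognormal") {
    sdlog <- sqrt(log(1 + (sd / mean)^2))
    rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    rnorm(n, mean, sd)
  }
  pmax(x, min)
}

.generate_emr <- function(ids, fall, los, effects, frailty = NULL) {
  n <- length(ids)
  if (is.null(frailty)) frailty <- rep(0, n)
  eff <- effects %||% fall_contrasts(male_shift = 0, age_shift = 0, los_factor = 1,
                                     icu_prob = 0.050, sedative_prob = 0.169,
                                     peridol_prob = 0.061,
                                     dept_probs = c(medicine = 0.573, major_surgery = 0.312,
                                                    minor_surgery = 0.113, others = 0.002),
                                     lab_shifts = numeric(0))
  base_dept <- c(medicine = 0.573, major_surgery = 0.312,
                 minor_surgery = 0.113, others = 0.002)
  # frailty enters exposures on the logit scale and shifted labs along the
  # direction of their group contrast, correlating covariates within groups
  frail_p <- function(p_group) stats::plogis(stats::qlogis(p_group) + frailty)
  male_p <- ifelse(fall == 1L, pmin(1, 0.492 + eff$male_shift), 0.492)
  sex <- ifelse(runif(n) < male_p, "male", "female")
  age <- round(pmin(pmax(rnorm(n, 69.5 + ifelse(fall == 1L, eff$age_shift, 0) +
                                 4 * frailty, 14), 18), 100))
  dept <- character(n)
  dept[fall == 0L] <- sample(names(base_dept), sum(fall == 0L), replace = TRUE, prob = base_dept)
  if (any(fall == 1L))
    dept[fall == 1L] <- sample(names(eff$dept_probs), sum(fall == 1L), replace = TRUE,
                               prob = eff$dept_probs)
  icu <- rbinom(n, 1L, frail_p(ifelse(fall == 1L, eff$icu_prob, 0.050)))
  sedative <- rbinom(n, 1L, frail_p(ifelse(fall == 1L, eff$sedative_prob, 0.169)))
  peridol <- rbinom(n, 1L, frail_p(ifelse(fall == 1L, eff$peridol_prob, 0.061)))
  emr <- data.frame(patient_id = ids, sex = sex, age = age, los = los,
                    department = dept, icu = icu, sedative = sedative,
                    peridol = peridol, stringsAsFactors = FALSE)
  sch <- .lab_schema()
  for (i in seq_len(nrow(sch))) {
    v <- sch$var[i]
    shift <- if (v %in% names(eff$lab_shifts)) eff$lab_shifts[[v]] else 0
    x <- .gen_continuous(n, sch$dist[i], sch$mean[i], sch$sd[i], sch$min[i])
    x <- x + 0.5 * sch$sd[i] * sign(shift) * frailty
    emr[[v]] <- round(pmax(x + ifelse(fall == 1L, shift, 0), sch$min[i]), 2)
  }
  emr[, c("patient_id", clinical_schema())]
}

#' Blank a fraction of vital/laboratory cells at random
#'
#' Emulates missing-at-random laboratory results. Only the continuous
#' vital/lab columns are eligible; identifiers, demographics, admission
#' variables and exposure flags are never blanked.
#'
#' @param emr clinical table as produced by [simulate_cohort()].
#' @param rate per-cell blanking probability, in `[0, 1)`.
#' @return the table with eligible cells set to `NA`.
#' @export
inject_missingness <- function(emr, rate) {
  check_number(rate, "missingness_rate", 0, 1, allow_upper = FALSE)
  if (rate == 0 || nrow(emr) == 0L) return(emr)
  eligible <- intersect(.lab_schema()$var, names(emr))
  for (v in eligible) {
    blank <- runif(nrow(emr)) < rate
    emr[[v]][blank] <- NA_real_
  }
  emr
}

#' Simulate a synthetic inpatient cohort
#'
#' Generates, deterministically for a given configuration, (a) event-triggered
#' RTLS location streams for every patient over their stay, (b) a 27-variable
#' clinical table with configurable faller/non-faller contrasts and
#' missing-at-random lab gaps, and (c) fall labels with a fall timestamp for
#' each faller. Faller movement is degraded over the final `ramp_days` days
#' before the fall (slower gait with proportionally longer dwells, fewer
#' trips) and the fall-day trip count is inflated by
#' `faller_distance_inflation`. The fall timestamp is placed immediately after
#' the faller's last recorded movement of the fall day, and `post_fall_days`
#' further days of events are still generated — censoring is downstream's job.
#'
#' @param config a [simulation_config()] object.
#' @return An object of class `fall_cohort`: list with `events` (data.frame
#'   `patient_id`, `timestamp` POSIXct UTC, `lat`, `lng`), `emr`, `labels`
#'   (`patient_id`, `fall`, `fall_timestamp`, `admission`, `discharge`) and
#'   the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fall_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  empty <- function() {
    list(events = data.frame(patient_id = character(0), timestamp = as_utc(numeric(0)),
                             lat = numeric(0), lng = numeric(0), stringsAsFactors = FALSE),
         emr = .generate_emr(character(0), integer(0), integer(0), config$clinical_effects),
         labels = data.frame(patient_id = character(0), fall = integer(0),
                             fall_timestamp = as_utc(numeric(0)),
                             admission = as_utc(numeric(0)), discharge = as_utc(numeric(0)),
                             stringsAsFactors = FALSE),
         config = config)
  }
  if (n == 0L) return(structure(empty(), class = "fall_cohort"))

  ids <- sprintf("P%04d", seq_len(n))
  n_fall <- round(n * config$fall_fraction)
  fall <- integer(n)
  if (n_fall > 0L) fall[sample.int(n, n_fall)] <- 1L

  frailty <- config$frailty_weight * rnorm(n)
  los_meanlog <- config$los_meanlog + 0.2 * frailty +
    ifelse(fall == 1L & !is.null(config$clinical_effects),
           log((config$clinical_effects$los_factor %||% 1)), 0)
  los <- pmin(pmax(round(rlnorm(n, los_meanlog, config$los_sdlog)), 1L), config$los_max)

  gait <- pmax(rnorm(n, config$base_gait_speed, config$gait_speed_sd),
               config$base_gait_speed / 4)
  activity <- rlnorm(n, 0, config$activity_sdlog)
  base_day <- as.numeric(as.POSIXct("2022-03-01", tz = "UTC"))
  admit_offset <- sample.int(60L, n, replace = TRUE) - 1L

  wps <- config$waypoints
  k <- nrow(wps)
  dmat <- .waypoint_distances(wps)
  ts_list <- vector("list", n); wp_list <- vector("list", n)
  fall_ts <- rep(NA_real_, n)
  admission <- numeric(n); discharge <- numeric(n)
  for (p in seq_len(n)) {
    day0 <- base_day + admit_offset[p] * 86400
    n_days <- los[p] + if (fall[p] == 1L) config$post_fall_days else 0L
    cur <- sample.int(k, 1L)
    day_ts <- vector("list", n_days); day_wp <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      w <- 0
      if (fall[p] == 1L) {
        gap <- los[p] - d
        w <- if (gap < 0) 1 else max(0, 1 - gap / config$ramp_days)
      }
      sf <- 1 - w * (1 - config$faller_speed_decline)
      af <- 1 - w * (1 - config$faller_activity_decline)
      infl <- if (fall[p] == 1L && d == los[p]) config$faller_distance_inflation else 1
      m_speed <- rlnorm(1L, 0, config$day_speed_sdlog)
      m_trips <- rlnorm(1L, 0, config$day_trips_sdlog)
      lambda <- config$trips_per_day * activity[p] * af * infl * m_trips
      n_trips <- rpois(1L, lambda)
      t0 <- day0 + (d - 1) * 86400 + (config$day_start_hour + runif(1)) * 3600
      pace <- sf * m_speed
      traj <- .sim_day(k, dmat, cur, n_trips, gait_speed = gait[p] * pace, t0 = t0,
                       p_active = config$p_active,
                       dwell_active_mean = config$dwell_active_mean,
                       dwell_rest_mean = config$dwell_rest_mean, dwell_scale = 1 / pace,
                       max_time = day0 + d * 86400 - 60, include_start = (d == 1L))
      cur <- traj$end_index
      day_ts[[d]] <- traj$timestamp; day_wp[[d]] <- traj$wp
      if (fall[p] == 1L && d == los[p]) {
        fall_ts[p] <- if (length(traj$timestamp) > 0) max(traj$timestamp) + 1
          else day0 + (d - 1) * 86400 + (config$day_start_hour + 1) * 3600
      }
    }
    ts_list[[p]] <- unlist(day_ts); wp_list[[p]] <- unlist(day_wp)
    admission[p] <- day0
    discharge[p] <- day0 + n_days * 86400
  }
  n_ev <- lengths(ts_list)
  wp_all <- unlist(wp_list)
  events <- data.frame(patient_id = rep(ids, n_ev),
                       timestamp = as_utc(unlist(ts_list)),
                       lat = wps$lat[wp_all], lng = wps$lng[wp_all],
                       stringsAsFactors = FALSE)

  emr <- .generate_emr(ids, fall, los, config$clinical_effects, frailty = frailty)
  emr <- inject_missingness(emr, config$missingness_rate)

  labels <- data.frame(patient_id = ids, fall = fall,
                       fall_timestamp = as_utc(fall_ts),
                       admission = as_utc(admission), discharge = as_utc(discharge),
                       stringsAsFactors = FALSE)
  structure(list(events = events, emr = emr, labels = labels, config = config),
            class = "fall_cohort")
}

#' @export
print.fall_cohort <- function(x, ...) {
  cat(sprintf("<fall_cohort> %d patients (%d fallers), %d RTLS events\n",
              nrow(x$labels), sum(x$labels$fall), nrow(x$events)))
  invisible(x)
}
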