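# Orchestration: delimited-text IO, input validation and the end-to-end
# simulate -> features -> train -> evaluate pipeline with a reproducibility
# manifest.

TIMESTAMP_FORMAT <- "%Y-%m-%dT%H:%M:%OS6"
TIMESTAMP_PARSE <- "%Y-%m-%dT%H:%M:%OS"

#' Write / read RTLS event streams as delimited text
#'
#' Events are stored as CSV with header `patient_id,timestamp,lat,lng`,
#' ISO-8601 UTC timestamps (microsecond precision) and decimal-degree
#' coordinates.
#'
#' @param events data.frame with `patient_id`, `timestamp`, `lat`, `lng`.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` the parsed
#'   data.frame.
#' @export
write_events <- function(events, path) {
  out <- data.table::as.data.table(events)
  out[, timestamp := format(timestamp, TIMESTAMP_FORMAT, tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("patient_id", "timestamp")))
  dt[, timestamp := as.POSIXct(timestamp, format = TIMESTAMP_PARSE, tz = "UTC")]
  as.data.frame(dt)
}

#' Write / read clinical and label tables as delimited text
#'
#' Missing cells are encoded as empty fields; label tables carry ISO-8601
#' fall timestamps.
#'
#' @param tab data.frame.
#' @param path file path.
#' @return `read_table_file` returns a data.frame.
#' @export
write_table_file <- function(tab, path) {
  out <- data.table::as.data.table(tab)
  for (v in names(out))
    if (inherits(out[[v]], "POSIXct"))
      out[[v]] <- format(out[[v]], TIMESTAMP_FORMAT, tz = "UTC")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  for (v in names(dt))
    if (is.character(dt[[v]]) && all(grepl("^\\d{4}-\\d{2}-\\d{2}T", dt[[v]][!is.na(dt[[v]])])) &&
        any(!is.na(dt[[v]])))
      dt[[v]] <- as.POSIXct(dt[[v]], format = TIMESTAMP_PARSE, tz = "UTC")
  as.data.frame(dt)
}

#' Validate pipeline inputs
#'
#' Schema and sanity checks on the event stream and label table: required
#' columns, parseable timestamps (fatal, with the offending line), coordinate
#' ranges (fatal), per-patient event counts and label consistency; unsorted
#' event rows produce a warning and are auto-sorted.
#'
#' @param events events data.frame (or path).
#' @param labels labels data.frame (or path), optional.
#' @return list with `errors` (character), `warnings` (character) and
#'   `events` (possibly re-sorted).
#' @export
validate_inputs <- function(events, labels = NULL) {
  errors <- character(0); warnings <- character(0)
  if (is.character(events)) {
    if (!file.exists(events)) stop("events file not found: ", events)
    events <- read_events(events)
  }
  if (is.character(labels)) labels <- read_table_file(labels)
  need <- c("patient_id", "timestamp", "lat", "lng")
  miss <- setdiff(need, names(events))
  if (length(miss))
    return(list(errors = paste("missing event columns:", paste(miss, collapse = ", ")),
                warnings = warnings, events = events))
  bad_ts <- which(is.na(events$timestamp))
  if (length(bad_ts))
    errors <- c(errors, sprintf("unparseable timestamp at line %d", bad_ts[1] + 1L))
  bad_lat <- which(!is.finite(events$lat) | abs(events$lat) > 90)
  bad_lng <- which(!is.finite(events$lng) | abs(events$lng) > 180)
  if (length(bad_lat))
    errors <- c(errors, sprintf("latitude out of [-90, 90] at line %d", bad_lat[1] + 1L))
  if (length(bad_lng))
    errors <- c(errors, sprintf("longitude out of [-180, 180] at line %d", bad_lng[1] + 1L))
  if (length(errors) == 0L) {
    dt <- as.data.table(events)
    unsorted <- dt[, .(bad = is.unsorted(as.numeric(timestamp))), by = patient_id]
    if (any(unsorted$bad)) {
      warnings <- c(warnings, "event rows were not sorted by timestamp within patient; auto-sorted")
      data.table::setorder(dt, patient_id, timestamp)
      events <- as.data.frame(dt)
    }
    few <- dt[, .N, by = patient_id][N < 2L]
    if (nrow(few))
      warnings <- c(warnings, sprintf("%d patient(s) have fewer than 2 events", nrow(few)))
    if (!is.null(labels)) {
      no_lab <- setdiff(unique(events$patient_id), labels$patient_id)
      if (length(no_lab))
        warnings <- c(warnings, sprintf("%d patient(s) with events but no label row", length(no_lab)))
    }
  }
  list(errors = errors, warnings = warnings, events = events)
}

#' Run the full fall-risk pipeline
#'
#' Simulates (or loads) a cohort, engineers the movement and clinical feature
#' tables, trains the clinical-only, RTLS-only and combined models on a
#' stratified 8:2 split, evaluates them with the paired bootstrap protocol
#' plus decision-curve and subgroup analyses, and writes every artefact with
#' a manifest sufficient to reproduce the run.
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a [simulation_config()], or `NULL` when loading data.
#' @param events,emr,labels input tables or file paths (used when
#'   `sim_config` is `NULL`).
#' @param thresholds velocity thresholds; `derive = TRUE` recomputes them
#'   from this cohort.
#' @param derive derive thresholds from the cohort velocity pool.
#' @param censor_mode fall censoring mode, see [censor_at_fall()].
#' @param split_seed seed of the 8:2 split and model training.
#' @param grid hyperparameter grid.
#' @param folds CV folds.
#' @param n_boot bootstrap iterations.
#' @return invisible list with the feature tables, fitted bundles,
#'   evaluation objects and file paths.
#' @export
run_pipeline <- function(out_dir, sim_config = NULL, events = NULL, emr = NULL,
                         labels = NULL, thresholds = velocity_thresholds(),
                         derive = FALSE, censor_mode = "strict",
                         split_seed = 1L, grid = default_grid(), folds = 10L,
                         n_boot = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(fmt, ...) message(sprintf(paste0("[rtlsfall] ", fmt), ...))

  if (!is.null(sim_config)) {
    log_line("stage simulate: n_patients = %d, seed = %d",
             sim_config$n_patients, sim_config$seed)
    cohort <- simulate_cohort(sim_config)
  } else {
    if (is.null(events) || is.null(emr) || is.null(labels))
      stop("run_pipeline: provide either sim_config or events + emr + labels")
    if (is.character(events) && !file.exists(events))
      stop("run_pipeline: events path does not exist: ", events)
    if (is.character(emr) && !file.exists(emr))
      stop("run_pipeline: emr path does not exist: ", emr)
    if (is.character(labels) && !file.exists(labels))
      stop("run_pipeline: labels path does not exist: ", labels)
    val <- validate_inputs(events, labels)
    if (length(val$errors)) stop("run_pipeline: ", paste(val$errors, collapse = "; "))
    for (w in val$warnings) warning(w, call. = FALSE)
    cohort <- structure(list(
      events = val$events,
      emr = if (is.character(emr)) read_table_file(emr) else emr,
      labels = if (is.character(labels)) read_table_file(labels) else labels,
      config = NULL), class = "fall_cohort")
  }
  write_events(cohort$events, file.path(out_dir, "events.csv"))
  write_table_file(cohort$emr, file.path(out_dir, "emr.csv"))
  write_table_file(cohort$labels, file.path(out_dir, "labels.csv"))

  log_line("stage rtls_features: %d patients in", nrow(cohort$labels))
  rt <- rtls_features(cohort, thresholds = thresholds, derive = derive,
                      censor_mode = censor_mode)
  for (i in seq_len(nrow(rt$exclusions)))
    log_line("  exclusion rule %s: removed %d, remaining %d",
             rt$exclusions$rule[i], rt$exclusions$n_removed[i],
             rt$exclusions$n_remaining[i])
  write_table_file(rt$features, file.path(out_dir, "rtls_features.csv"))

  log_line("stage clinical_features")
  cohort_kept <- cohort
  cohort_kept$emr <- cohort$emr[cohort$emr$patient_id %in% rt$labels$patient_id, , drop = FALSE]
  cl <- clinical_features(cohort_kept)
  write_table_file(cl$features, file.path(out_dir, "clinical_features.csv"))

  # align all tables on the retained patients
  ids <- rt$labels$patient_id
  rx <- rt$features[match(ids, rt$features$patient_id), , drop = FALSE]
  cx <- cl$features[match(ids, cl$features$patient_id), , drop = FALSE]
  y <- rt$labels$fall
  rtls_cols <- rtls_feature_names()
  feats <- list(
    clinical = cx,
    rtls = rx[, c("patient_id", rtls_cols)],
    combined = cbind(cx, rx[, rtls_cols, drop = FALSE]))

  log_line("stage train: %d patients, %d fallers", length(y), sum(y))
  sp <- split_cohort(feats$combined, y, ratio = 0.8, seed = split_seed)
  bundles <- lapply(names(feats), function(fs) {
    train_model(feats[[fs]][sp$train, , drop = FALSE], y[sp$train],
                feature_set = fs, grid = grid, folds = folds, seed = split_seed)
  })
  names(bundles) <- names(feats)

  log_line("stage evaluate: test n = %d, n_boot = %d", length(sp$test), n_boot)
  probs <- lapply(names(feats), function(fs)
    predict_risk(bundles[[fs]], feats[[fs]][sp$test, , drop = FALSE])$prob)
  names(probs) <- names(feats)
  cutoffs <- vapply(bundles, `[[`, numeric(1), "cutoff")
  boot <- bootstrap_compare(probs, y[sp$test], cutoffs = cutoffs,
                            metrics = c("auroc", "auprc", "brier"),
                            n_boot = n_boot, seed = split_seed)
  dca <- decision_curve(y[sp$test], probs)
  axes <- subgroup_axes(cl$imputed[match(ids[sp$test], cl$imputed$patient_id), ])
  subgroups <- subgroup_auroc(probs$combined, y[sp$test], axes)
  importance <- feature_importance(bundles$combined,
                                   feats$combined[sp$test, , drop = FALSE])

  write_table_file(boot$summary, file.path(out_dir, "metrics.csv"))
  write_table_file(as.data.frame(dca), file.path(out_dir, "decision_curve.csv"))
  write_table_file(subgroups, file.path(out_dir, "subgroups.csv"))
  write_table_file(importance, file.path(out_dir, "importance.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("rtlsfall")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"),
    split_seed = split_seed, folds = folds, n_boot = n_boot,
    censor_mode = censor_mode, derive_thresholds = derive,
    thresholds = unclass(rt$thresholds),
    grid = as.list(grid),
    simulation = if (!is.null(sim_config)) {
      s <- unclass(sim_config); s$waypoints <- NULL
      s$clinical_effects <- if (is.null(s$clinical_effects)) "null" else
        lapply(s$clinical_effects, as.list)
      s
    } else "external data")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  jsonlite::write_json(
    list(metrics = boot$summary,
         kruskal_p = lapply(boot$tests, function(t) t$kruskal_p)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, rtls = rt, clinical = cl, split = sp,
                 bundles = bundles, probs = probs, bootstrap = boot, dca = dca,
                 subgroups = subgroups, importance = importance,
                 out_dir = out_dir))
}
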