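# Gradient-boosted fall-risk classifiers: stratified split, 10-fold CV grid
# search, Youden-index operating cutoff.

#' Default hyperparameter grid
#'
#' Small documented grid over tree depth, learning rate, boosting rounds and
#' minimum child weight. Any data.frame with columns `max_depth`, `eta`,
#' `nrounds`, `min_child_weight` can be supplied instead.
#' @return data.frame of grid points.
#' @export
default_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1),
              nrounds = c(100L, 300L), min_child_weight = c(1, 5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Compact hyperparameter grid for simulation studies
#'
#' A single moderate operating point used by the package's repeated-seed
#' simulation checks, where refitting the full grid for every seed and model
#' would dominate runtime without changing the qualitative conclusions.
#' @return one-row data.frame.
#' @export
small_grid <- function() {
  data.frame(max_depth = 3L, eta = 0.1, nrounds = 150L, min_child_weight = 1)
}

#' Stratified train/test split
#'
#' Splits rows into train and test with the positive/negative class balance
#' preserved on both sides; reproducible under `seed`.
#'
#' @param feature_table data.frame of features (any columns).
#' @param labels 0/1 vector aligned with `feature_table` rows.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return list with `train`, `test` (row indices), and the inputs split as
#'   `train_x`/`train_y`/`test_x`/`test_y`.
#' @export
split_cohort <- function(feature_table, labels, ratio = 0.8, seed = 1L) {
  stopifnot(nrow(feature_table) == length(labels))
  if (length(labels) < 10L) stop("split_cohort: need at least 10 labelled rows")
  check_number(ratio, "ratio", 0, 1, allow_lower = FALSE, allow_upper = FALSE)
  set.seed(seed)
  idx_train <- integer(0)
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    n_tr <- round(length(rows) * ratio)
    if (n_tr == 0L || n_tr == length(rows))
      stop("split_cohort: a class would be absent from one side at this ratio")
    idx_train <- c(idx_train, sample(rows, n_tr))
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(labels), idx_train)
  list(train = idx_train, test = idx_test,
       train_x = feature_table[idx_train, , drop = FALSE], train_y = labels[idx_train],
       test_x = feature_table[idx_test, , drop = FALSE], test_y = labels[idx_test])
}

# stratified fold assignment: every fold carries both classes when feasible
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- sample(which(labels == cl))
    fold[rows] <- rep_len(seq_len(folds), length(rows))
  }
  fold
}

#' Youden-index operating cutoff
#'
#' Maximises J = sensitivity + specificity - 1 over the observed
#' probabilities used as thresholds (calls are positive at prob >= cutoff);
#' ties resolve to the lowest threshold.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 outcomes (both classes required).
#' @return list with `cutoff` (probability threshold) and `j` (achieved
#'   Youden J statistic).
#' @export
youden_cutoff <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  if (length(unique(labels)) < 2L) stop("youden_cutoff: both classes required")
  th <- sort(unique(probs))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  j <- vapply(th, function(t) {
    sens <- sum(probs >= t & labels == 1L) / np
    spec <- sum(probs < t & labels == 0L) / nn
    sens + spec - 1
  }, numeric(1))
  best <- which(j == max(j))[1L]  # th sorted ascending: first max = lowest threshold
  list(cutoff = th[best], j = max(j))
}

xgb_matrix <- function(x, y = NULL) {
  m <- as.matrix(x[, setdiff(colnames(x), "patient_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (is.null(y)) xgboost::xgb.DMatrix(m, nthread = 1) else
    xgboost::xgb.DMatrix(m, label = y, nthread = 1)
}

#' Train one fall-risk model
#'
#' Grid search over boosted-tree hyperparameters by stratified k-fold
#' cross-validation on the training set, selecting the grid point with the
#' highest mean out-of-fold AUROC; the winner is refitted on all training
#' rows, and the operating cutoff is chosen by the Youden index on the
#' winner's out-of-fold predictions (never on test data).
#'
#' @param train_x training features (data.frame; a `patient_id` column is
#'   ignored).
#' @param train_y 0/1 training labels.
#' @param feature_set tag: `"clinical"`, `"rtls"` or `"combined"`.
#' @param grid hyperparameter grid (see [default_grid()]).
#' @param folds number of CV folds.
#' @param seed seed controlling fold assignment (boosting itself is
#'   deterministic single-threaded).
#' @return object of class `fall_model`: the fitted booster, chosen
#'   hyperparameters, Youden cutoff and J, feature manifest, out-of-fold
#'   probabilities and CV AUROC per grid point.
#' @export
train_model <- function(train_x, train_y, feature_set = c("combined", "clinical", "rtls"),
                        grid = default_grid(), folds = 10L, seed = 1L) {
  feature_set <- match.arg(feature_set)
  if (length(unique(train_y)) < 2L) stop("train_model: training data needs both classes")
  if (nrow(grid) == 0L) stop("train_model: empty hyperparameter grid")
  set.seed(seed)
  fold <- stratified_folds(train_y, folds)
  manifest <- setdiff(colnames(train_x), "patient_id")
  xm <- as.matrix(train_x[, manifest, drop = FALSE])
  storage.mode(xm) <- "double"

  oof <- matrix(NA_real_, nrow(grid), length(train_y))
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(train_y[!tr])) < 2L) { fold_auc[f] <- NA_real_; next }
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = grid$max_depth[g],
                      eta = grid$eta[g], min_child_weight = grid$min_child_weight[g],
                      nthread = 1),
        data = xgboost::xgb.DMatrix(xm[tr, , drop = FALSE], label = train_y[tr], nthread = 1),
        nrounds = grid$nrounds[g], verbose = 0)
      p <- predict(bst, xgboost::xgb.DMatrix(xm[!tr, , drop = FALSE], nthread = 1))
      oof[g, !tr] <- p
      fold_auc[f] <- metric("auroc", train_y[!tr], p)
    }
    cv_auc[g] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = grid$max_depth[best],
                  eta = grid$eta[best], min_child_weight = grid$min_child_weight[best],
                  nthread = 1),
    data = xgboost::xgb.DMatrix(xm, label = train_y, nthread = 1),
    nrounds = grid$nrounds[best], verbose = 0)
  oof_best <- oof[best, ]
  yd <- youden_cutoff(oof_best[!is.na(oof_best)], train_y[!is.na(oof_best)])
  structure(list(feature_set = feature_set, booster = booster,
                 params = grid[best, , drop = FALSE], cv_auroc = cv_auc,
                 grid = grid, youden = yd, cutoff = yd$cutoff,
                 manifest = manifest, oof_probs = oof_best, seed = seed),
            class = "fall_model")
}

#' Predict fall risk with a fitted model
#'
#' @param bundle a `fall_model`.
#' @param feature_rows data.frame whose columns (besides `patient_id`) must
#'   match the training manifest; column order is aligned by name.
#' @return data.frame with `prob` and `call` (1 when `prob >= cutoff`).
#' @export
predict_risk <- function(bundle, feature_rows) {
  stopifnot(inherits(bundle, "fall_model"))
  cols <- setdiff(colnames(feature_rows), "patient_id")
  missing <- setdiff(bundle$manifest, cols)
  extra <- setdiff(cols, bundle$manifest)
  if (length(missing) || length(extra))
    stop("predict_risk: feature columns do not match the training manifest",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  m <- as.matrix(feature_rows[, bundle$manifest, drop = FALSE])
  storage.mode(m) <- "double"
  p <- predict(bundle$booster, xgboost::xgb.DMatrix(m, nthread = 1))
  data.frame(prob = p, call = as.integer(p >= bundle$cutoff))
}

#' @export
print.fall_model <- function(x, ...) {
  cat(sprintf("<fall_model:%s> %d features; cutoff %.3f (J = %.3f); CV AUROC %.3f\n",
              x$feature_set, length(x$manifest), x$cutoff, x$youden$j,
              max(x$cv_auroc, na.rm = TRUE)))
  invisible(x)
}
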