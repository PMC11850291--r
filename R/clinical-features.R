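# Clinical feature pipeline: availability filter, first-measurement
# selection, KNN imputation and model encoding.

#' Filter variables by availability
#'
#' Keeps the columns whose non-missing fraction across patients is at least
#' `min_availability` (default: the 70% rule).
#'
#' @param raw_emr per-patient clinical table.
#' @param min_availability minimum non-missing proportion.
#' @param protect columns never dropped regardless of availability
#'   (identifiers and the label by default).
#' @return list with `table` (kept columns) and `report` (data.frame
#'   `variable`, `available`, `kept`).
#' @export
select_available <- function(raw_emr, min_availability = 0.70,
                             protect = c("patient_id", "fall")) {
  if (nrow(raw_emr) == 0L) stop("select_available: empty table")
  avail <- vapply(raw_emr, function(x) mean(!is.na(x)), numeric(1))
  kept <- avail >= min_availability | names(raw_emr) %in% protect
  list(table = raw_emr[, kept, drop = FALSE],
       report = data.frame(variable = names(raw_emr), available = unname(avail),
                           kept = unname(kept), stringsAsFactors = FALSE))
}

#' Select the first measurement per patient and variable
#'
#' When a variable was measured repeatedly, the earliest-timestamp value is
#' used for modelling. Timestamp ties are broken by input order.
#'
#' @param measurements long-format data.frame with `patient_id`, `variable`,
#'   `timestamp`, `value`.
#' @return data.frame with one row per patient-variable pair.
#' @export
first_measurement <- function(measurements) {
  need <- c("patient_id", "variable", "timestamp", "value")
  if (!all(need %in% names(measurements)))
    stop("first_measurement: need columns patient_id, variable, timestamp, value")
  dt <- as.data.table(measurements)
  out <- dt[order(as.numeric(timestamp)),
            .(timestamp = timestamp[1L], value = value[1L]),
            by = .(patient_id, variable)]
  data.table::setorder(out, patient_id, variable)
  as.data.frame(out)
}

#' K-nearest-neighbour imputation
#'
#' Replaces each missing numeric cell by the mean of that column over the
#' `k` nearest rows, with distances computed as the root mean squared
#' difference over mutually observed numeric features after z-scoring each
#' column on its observed values. Neighbours are restricted to rows where the
#' target column is observed. Non-numeric columns (categorical/binary stored
#' as character or factor) are imputed by the mode of the same `k`
#' neighbours. Observed cells are never touched; the operation is
#' deterministic (ties broken by row order) and idempotent.
#'
#' @param tab data.frame; `id_cols` are carried through untouched.
#' @param k neighbour count.
#' @param id_cols columns excluded from both distance and imputation.
#' @return the completed data.frame.
#' @export
knn_impute <- function(tab, k = 5L, id_cols = "patient_id") {
  if (nrow(tab) <= k)
    stop(sprintf("knn_impute: need more than k = %d rows", k))
  feat_cols <- setdiff(names(tab), id_cols)
  num_cols <- feat_cols[vapply(tab[feat_cols], is.numeric, logical(1))]
  X <- as.matrix(tab[num_cols])
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  obs <- !is.na(Z)

  all_missing <- rowSums(obs) == 0L
  if (any(all_missing))
    warning(sprintf("%d row(s) missing every numeric value: column-mean fallback",
                    sum(all_missing)))

  neighbour_order <- function(i) {
    d2 <- rowSums(sweep(Z, 2, Z[i, ], "-")^2, na.rm = TRUE)
    m <- as.numeric(obs %*% obs[i, ])  # mutual feature counts
    d <- sqrt(d2 / m)
    d[m == 0] <- Inf
    d[i] <- Inf
    order(d)  # stable: ties by row order
  }

  out <- tab
  rows_missing <- which(rowSums(is.na(tab[feat_cols])) > 0L)
  for (i in rows_missing) {
    ord <- if (all_missing[i]) integer(0) else neighbour_order(i)
    miss_v <- feat_cols[vapply(tab[feat_cols], function(col) is.na(col[i]), logical(1))]
    for (v in miss_v) {
      if (v %in% num_cols) {
        cand <- ord[!is.na(X[ord, v])]
        out[[v]][i] <- if (length(cand) == 0L) mu[[v]]
          else mean(X[head(cand, k), v])
      } else {
        cand <- ord[!is.na(tab[[v]][ord])]
        if (length(cand) == 0L) cand <- which(!is.na(tab[[v]]))
        vals <- tab[[v]][head(cand, k)]
        tabv <- sort(table(vals), decreasing = TRUE)
        out[[v]][i] <- names(tabv)[1L]
      }
    }
  }
  out
}

#' Encode the clinical table as a numeric design matrix
#'
#' One-hot encodes the department category (4 columns), maps binaries to 0/1
#' and passes numerics through, in a fixed documented column order; the
#' 27-variable schema yields a 30-column design.
#'
#' @param tab complete clinical table ([knn_impute()] output) with the
#'   [clinical_schema()] columns.
#' @return data.frame with `patient_id` plus 30 numeric columns.
#' @export
encode_for_model <- function(tab) {
  depts <- c("medicine", "major_surgery", "minor_surgery", "others")
  if (anyNA(tab)) stop("encode_for_model: table still has missing values")
  unknown <- setdiff(unique(tab$department), depts)
  if (length(unknown))
    stop("encode_for_model: unknown department category: ",
         paste(unknown, collapse = ", "))
  out <- data.frame(patient_id = tab$patient_id,
                    sex = as.numeric(tab$sex == "male"),
                    age = as.numeric(tab$age), los = as.numeric(tab$los),
                    stringsAsFactors = FALSE)
  for (d in depts) out[[paste0("dept_", d)]] <- as.numeric(tab$department == d)
  for (v in c("icu", "sedative", "peridol")) out[[v]] <- as.numeric(tab[[v]])
  for (v in setdiff(clinical_schema(),
                    c("sex", "age", "los", "department", "icu", "sedative", "peridol")))
    out[[v]] <- as.numeric(tab[[v]])
  out
}

#' Clinical feature pipeline for a cohort
#'
#' Applies the availability filter, KNN imputation and model encoding to a
#' cohort's clinical table.
#'
#' @param cohort a `fall_cohort` (or list with `emr`).
#' @param min_availability availability threshold, see [select_available()].
#' @param k imputation neighbour count.
#' @return list with `features` (encoded numeric design), `imputed` (the
#'   completed 27-variable table) and `availability` (report).
#' @export
clinical_features <- function(cohort, min_availability = 0.70, k = 5L) {
  sel <- select_available(cohort$emr, min_availability = min_availability)
  imputed <- knn_impute(sel$table, k = k)
  list(features = encode_for_model(imputed), imputed = imputed,
       availability = sel$report)
}
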