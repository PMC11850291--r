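# Evaluation protocol: classification metrics, paired bootstrap comparison
# with Kruskal-Wallis + Dunn post hoc, decision-curve analysis, DeLong
# tests, subgroup AUROC, baseline-table statistics, association screening
# and feature-importance reporting.

METRIC_NAMES <- c("auroc", "auprc", "brier", "accuracy", "ppv",
                  "sensitivity", "specificity", "f1")

auroc_rank <- function(labels, probs) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(probs)  # average ranks give 0.5 credit to ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

auprc_step <- function(labels, probs) {
  np <- sum(labels == 1L)
  if (np == 0L) return(NA_real_)
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]; p <- probs[ord]
  tp <- cumsum(y == 1L)
  prec <- tp / seq_along(y)
  rec <- tp / np
  # evaluate at the last index of each tied probability block
  last <- c(p[-1] != p[-length(p)], TRUE)
  prec <- prec[last]; rec <- rec[last]
  sum(diff(c(0, rec)) * prec)
}

confusion_metrics <- function(labels, calls) {
  tp <- sum(calls == 1L & labels == 1L); fp <- sum(calls == 1L & labels == 0L)
  tn <- sum(calls == 0L & labels == 0L); fn <- sum(calls == 0L & labels == 1L)
  c(accuracy = (tp + tn) / length(labels),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

#' Classification performance metric
#'
#' AUROC is the probability of concordance (ties credited 0.5), AUPRC the
#' non-interpolated step area under the precision-recall curve, Brier the
#' mean squared error of the probabilities; accuracy, PPV, sensitivity,
#' specificity and F1 are computed from the confusion matrix at `cutoff`
#' (calls positive when `prob >= cutoff`).
#'
#' @param name one of `"auroc"`, `"auprc"`, `"brier"`, `"accuracy"`,
#'   `"ppv"`, `"sensitivity"`, `"specificity"`, `"f1"`.
#' @param labels 0/1 outcomes.
#' @param probs predicted probabilities.
#' @param cutoff probability cutoff for the threshold metrics.
#' @return numeric scalar.
#' @export
metric <- function(name, labels, probs, cutoff = 0.5) {
  name <- match.arg(name, METRIC_NAMES)
  labels <- as.integer(labels)
  switch(name,
         auroc = auroc_rank(labels, probs),
         auprc = auprc_step(labels, probs),
         brier = mean((probs - labels)^2),
         confusion_metrics(labels, as.integer(probs >= cutoff))[[name]])
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise rank-sum z-tests on the pooled ranks with tie correction;
#' p-values are Bonferroni-adjusted for the number of pairwise comparisons.
#'
#' @param values numeric vector of pooled observations.
#' @param groups group membership, same length.
#' @return data.frame with one row per pair: `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  g <- unique(groups)
  if (length(g) < 2L) stop("dunn_test: need at least two groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)[g]
  n <- tapply(r, groups, length)[g]
  pairs <- utils::combn(g, 2L)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = NA_real_,
                    p_unadjusted = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- 2 * pnorm(-abs(z))
    res$z[i] <- z
    res$p_unadjusted[i] <- p
    res$p_adjusted[i] <- min(1, p * m)
  }
  res
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Paired bootstrap comparison of model performance
#'
#' Resamples the test set with replacement `n_boot` times using identical
#' resample indices across models (paired comparison); single-class
#' resamples are rejected and redrawn so every iteration contributes. For
#' every model and metric it reports the full-test-set point estimate and
#' percentile 95% CI over the bootstrap distribution, then compares the
#' models' per-iteration distributions with a Kruskal-Wallis test followed
#' by Dunn's pairwise tests (Bonferroni-adjusted), flagging significance
#' tiers (* / ** / ***).
#'
#' @param probs_list named list (one element per model) of predicted
#'   probabilities on the shared test set.
#' @param labels 0/1 test outcomes.
#' @param cutoffs named numeric vector of per-model probability cutoffs for
#'   the threshold metrics (defaults to 0.5 for all).
#' @param metrics metric names to evaluate.
#' @param n_boot number of bootstrap iterations (>= 2).
#' @param seed integer seed for the resampling.
#' @return object of class `fall_bootstrap`: `summary` (point estimates and
#'   CIs), `distributions` (list of n_boot x n_model matrices), `tests`
#'   (Kruskal-Wallis p and Dunn table per metric).
#' @export
bootstrap_compare <- function(probs_list, labels, cutoffs = NULL,
                              metrics = c("auroc", "auprc", "brier"),
                              n_boot = 1000L, seed = 1L) {
  if (n_boot < 2L) stop("bootstrap_compare: n_boot must be at least 2")
  stopifnot(is.list(probs_list), length(probs_list) >= 1L)
  models <- names(probs_list)
  if (is.null(cutoffs)) cutoffs <- setNames(rep(0.5, length(models)), models)
  n <- length(labels)
  set.seed(seed)
  idx <- matrix(0L, n_boot, n)
  for (b in seq_len(n_boot)) {
    repeat {
      s <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[s])) == 2L) break
    }
    idx[b, ] <- s
  }
  dists <- lapply(metrics, function(mt) {
    out <- matrix(NA_real_, n_boot, length(models),
                  dimnames = list(NULL, models))
    for (mod in models) {
      p <- probs_list[[mod]]
      out[, mod] <- vapply(seq_len(n_boot), function(b) {
        s <- idx[b, ]
        metric(mt, labels[s], p[s], cutoff = cutoffs[[mod]])
      }, numeric(1))
    }
    out
  })
  names(dists) <- metrics

  summary <- do.call(rbind, lapply(metrics, function(mt) {
    do.call(rbind, lapply(models, function(mod) {
      point <- metric(mt, labels, probs_list[[mod]], cutoff = cutoffs[[mod]])
      ci <- quantile(dists[[mt]][, mod], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      data.frame(model = mod, metric = mt, point = point,
                 ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }))
  }))

  tests <- lapply(metrics, function(mt) {
    d <- dists[[mt]]
    if (ncol(d) < 2L) return(NULL)
    vals <- as.vector(d)
    grp <- rep(colnames(d), each = nrow(d))
    kw <- kruskal.test(split(vals, grp))
    dn <- dunn_test(vals, grp)
    dn$stars <- significance_stars(dn$p_adjusted)
    list(kruskal_p = kw$p.value, kruskal_statistic = unname(kw$statistic), dunn = dn)
  })
  names(tests) <- metrics
  structure(list(summary = summary, distributions = dists, tests = tests,
                 n_boot = n_boot, cutoffs = cutoffs),
            class = "fall_bootstrap")
}

#' @export
print.fall_bootstrap <- function(x, ...) {
  cat(sprintf("<fall_bootstrap> %d iterations\n", x$n_boot))
  s <- x$summary
  s$point <- sprintf("%.3f (%.3f-%.3f)", s$point, s$ci_low, s$ci_high)
  print(s[, c("model", "metric", "point")], row.names = FALSE)
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of each model over a grid of decision thresholds,
#' NB(p_t) = TP/n - (FP/n) p_t / (1 - p_t), classifying positive at
#' prob >= p_t, with treat-all and treat-none reference policies.
#'
#' @param labels 0/1 outcomes.
#' @param probs_list named list of predicted probabilities per model.
#' @param thresholds decision thresholds in (0, 1); values outside are
#'   dropped.
#' @return data.frame of class `decision_curve` with `threshold`, `model`
#'   (including `treat_all`, `treat_none`) and `net_benefit`.
#' @export
decision_curve <- function(labels, probs_list,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  prev <- mean(labels == 1L)
  nb_model <- function(probs, t) {
    tp <- sum(probs >= t & labels == 1L)
    fp <- sum(probs >= t & labels == 0L)
    tp / n - (fp / n) * t / (1 - t)
  }
  rows <- lapply(names(probs_list), function(mod) {
    data.frame(threshold = thresholds, model = mod,
               net_benefit = vapply(thresholds, function(t)
                 nb_model(probs_list[[mod]], t), numeric(1)),
               stringsAsFactors = FALSE)
  })
  ref <- rbind(
    data.frame(threshold = thresholds, model = "treat_all",
               net_benefit = prev - (1 - prev) * thresholds / (1 - thresholds)),
    data.frame(threshold = thresholds, model = "treat_none", net_benefit = 0))
  out <- rbind(do.call(rbind, rows), ref)
  class(out) <- c("decision_curve", "data.frame")
  out
}

# DeLong placement values and variance components for one set of predictions
delong_placements <- function(labels, probs) {
  pos <- probs[labels == 1L]; neg <- probs[labels == 0L]
  np <- length(pos); nn <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / nn, numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / np, numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong's test for two correlated AUROCs
#'
#' Compares the AUROCs of two models evaluated on the same subjects using
#' the placement-value covariance estimator, with a two-sided normal
#' reference for the z statistic.
#'
#' @param labels 0/1 outcomes.
#' @param probs_a,probs_b paired predictions of the two models.
#' @return list with `auroc_a`, `auroc_b`, `z`, `p`.
#' @export
delong_test <- function(labels, probs_a, probs_b) {
  stopifnot(length(labels) == length(probs_a), length(labels) == length(probs_b))
  if (length(unique(labels)) < 2L) stop("delong_test: both classes required")
  pa <- delong_placements(labels, probs_a)
  pb <- delong_placements(labels, probs_b)
  np <- length(pa$v10); nn <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / np +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nn
  if (v <= 0 || !is.finite(v)) {
    warning("delong_test: zero variance of the AUROC difference; p = 1")
    return(list(auroc_a = pa$auc, auroc_b = pb$auc, z = 0, p = 1))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auroc_a = pa$auc, auroc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

# DeLong variance of one AUROC (for comparisons across independent strata)
delong_variance <- function(labels, probs) {
  pl <- delong_placements(labels, probs)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' Subgroup AUROC analysis
#'
#' Computes the AUROC of a model within the two strata of each subgroup axis
#' (e.g., age <= 65 vs > 65, sex, LOS <= 7 vs > 7 days) and compares the two
#' strata with a DeLong-variance z-test (strata are disjoint, hence
#' independent). Strata missing a class are flagged, not computed.
#'
#' @param probs predicted probabilities on the test set.
#' @param labels 0/1 test outcomes.
#' @param strata data.frame of factor/character columns, one per axis,
#'   aligned with `labels`.
#' @return data.frame with one row per axis: per-stratum n and AUROC, z, p
#'   and a `flag` for non-computable strata.
#' @export
subgroup_auroc <- function(probs, labels, strata) {
  stopifnot(nrow(strata) == length(labels))
  out <- lapply(names(strata), function(ax) {
    lv <- sort(unique(as.character(strata[[ax]])))
    if (length(lv) != 2L)
      return(data.frame(axis = ax, level1 = NA, level2 = NA, n1 = NA, n2 = NA,
                        auroc1 = NA, auroc2 = NA, z = NA, p = NA,
                        flag = "axis must have exactly two strata"))
    in1 <- strata[[ax]] == lv[1]; in2 <- !in1
    ok1 <- length(unique(labels[in1])) == 2L
    ok2 <- length(unique(labels[in2])) == 2L
    a1 <- if (ok1) auroc_rank(labels[in1], probs[in1]) else NA_real_
    a2 <- if (ok2) auroc_rank(labels[in2], probs[in2]) else NA_real_
    z <- p <- NA_real_; flag <- ""
    if (ok1 && ok2) {
      v <- delong_variance(labels[in1], probs[in1]) +
        delong_variance(labels[in2], probs[in2])
      if (is.finite(v) && v > 0) {
        z <- (a1 - a2) / sqrt(v); p <- 2 * pnorm(-abs(z))
      } else flag <- "zero variance"
    } else flag <- "stratum with a single outcome class"
    data.frame(axis = ax, level1 = lv[1], level2 = lv[2],
               n1 = sum(in1), n2 = sum(in2), auroc1 = a1, auroc2 = a2,
               z = z, p = p, flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standard subgroup axes for the fall-risk evaluation
#'
#' Dichotomises age at 65 years (a 65-year-old lands in the lower stratum),
#' sex, and length of stay at 7 days.
#'
#' @param clinical clinical table with `age`, `sex`, `los` (numeric sex 0/1
#'   or character).
#' @return data.frame of factors `age_group`, `sex`, `los_group`.
#' @export
subgroup_axes <- function(clinical) {
  sex <- if (is.numeric(clinical$sex))
    ifelse(clinical$sex == 1, "male", "female") else as.character(clinical$sex)
  data.frame(age_group = ifelse(clinical$age <= 65, "age<=65", "age>65"),
             sex = sex,
             los_group = ifelse(clinical$los <= 7, "los<=7", "los>7"),
             stringsAsFactors = FALSE)
}

#' Baseline characteristics comparison table
#'
#' For every variable, compares fallers and non-fallers the way clinical
#' baseline tables do: binary/categorical variables with a chi-square test
#' and n (%) formatting; continuous variables gated by a Shapiro-Wilk
#' normality test (alpha = 0.05 in both groups) choosing a t-test with
#' mean (SD) formatting when normal and a Mann-Whitney U test with
#' median [IQR] otherwise.
#'
#' @param tab data.frame of variables (no identifiers).
#' @param labels 0/1 group membership aligned with rows.
#' @return data.frame with `variable`, `type`, `test`, formatted group
#'   summaries and `p`.
#' @export
baseline_table <- function(tab, labels) {
  stopifnot(nrow(tab) == length(labels))
  fmt_cont <- function(x, normal) {
    if (normal) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
    else sprintf("%.1f [%.1f-%.1f]", median(x, na.rm = TRUE),
                 quantile(x, 0.25, na.rm = TRUE), quantile(x, 0.75, na.rm = TRUE))
  }
  rows <- lapply(names(tab), function(v) {
    x <- tab[[v]]
    if (all(is.na(x)))
      return(data.frame(variable = v, type = "omitted", test = NA, overall = NA,
                        group1 = NA, group0 = NA, p = NA,
                        note = "all values missing", stringsAsFactors = FALSE))
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      length(unique(x[!is.na(x)])) <= 2L
    if (categorical) {
      ct <- table(as.character(x), labels)
      p <- tryCatch(suppressWarnings(chisq.test(ct, correct = FALSE)$p.value),
                    error = function(e) NA_real_)
      top <- names(sort(table(as.character(x)), decreasing = TRUE))[1L]
      fmt_bin <- function(sel) {
        xx <- as.character(x[sel])
        sprintf("%d (%.1f%%)", sum(xx == top, na.rm = TRUE),
                100 * mean(xx == top, na.rm = TRUE))
      }
      data.frame(variable = v, type = "categorical", test = "chi-square",
                 overall = fmt_bin(rep(TRUE, length(x))),
                 group1 = fmt_bin(labels == 1L), group0 = fmt_bin(labels == 0L),
                 p = p, note = paste0("level shown: ", top), stringsAsFactors = FALSE)
    } else {
      sw_ok <- function(xx) {
        xx <- xx[!is.na(xx)]
        if (length(xx) < 3L || length(unique(xx)) < 3L) return(FALSE)
        shapiro.test(if (length(xx) > 5000) sample(xx, 5000) else xx)$p.value >= 0.05
      }
      normal <- sw_ok(x[labels == 1L]) && sw_ok(x[labels == 0L])
      p <- if (normal) t.test(x[labels == 1L], x[labels == 0L])$p.value
        else suppressWarnings(wilcox.test(x[labels == 1L], x[labels == 0L])$p.value)
      data.frame(variable = v, type = "continuous",
                 test = if (normal) "t-test" else "mann-whitney",
                 overall = fmt_cont(x, normal), group1 = fmt_cont(x[labels == 1L], normal),
                 group0 = fmt_cont(x[labels == 0L], normal), p = p, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Screen clinical-movement feature associations
#'
#' Pearson correlation for continuous clinical x movement feature pairs and
#' Kruskal-Wallis tests for categorical clinical x movement pairs, ranked by
#' |r| and H respectively; the top `k` pairs of each family are returned.
#' Constant columns are skipped.
#'
#' @param clinical data.frame of clinical features (numeric = continuous,
#'   character/factor or 0/1 = categorical).
#' @param rtls data.frame of numeric movement features.
#' @param k pairs returned per test family.
#' @return data.frame with `clinical`, `rtls`, `test`, `statistic`, `p`.
#' @export
association_screen <- function(clinical, rtls, k = 6L) {
  is_cat <- function(x) is.character(x) || is.factor(x) ||
    length(unique(x[!is.na(x)])) <= 2L
  const <- function(x) length(unique(x[!is.na(x)])) < 2L
  cont_vars <- names(clinical)[!vapply(clinical, is_cat, logical(1))]
  cat_vars <- names(clinical)[vapply(clinical, is_cat, logical(1))]
  rtls_vars <- names(rtls)[vapply(rtls, is.numeric, logical(1))]
  rows <- list()
  for (cv in cont_vars) {
    if (const(clinical[[cv]])) next
    for (rv in rtls_vars) {
      if (const(rtls[[rv]])) next
      ct <- suppressWarnings(cor.test(clinical[[cv]], rtls[[rv]], method = "pearson"))
      rows[[length(rows) + 1L]] <- data.frame(
        clinical = cv, rtls = rv, test = "pearson",
        statistic = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  for (cv in cat_vars) {
    if (const(clinical[[cv]])) next
    for (rv in rtls_vars) {
      if (const(rtls[[rv]])) next
      kw <- kruskal.test(rtls[[rv]], factor(clinical[[cv]]))
      rows[[length(rows) + 1L]] <- data.frame(
        clinical = cv, rtls = rv, test = "kruskal-wallis",
        statistic = unname(kw$statistic), p = kw$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  pe <- res[res$test == "pearson", , drop = FALSE]
  pe <- pe[order(-abs(pe$statistic)), , drop = FALSE]
  kw <- res[res$test == "kruskal-wallis", , drop = FALSE]
  kw <- kw[order(-kw$statistic), , drop = FALSE]
  out <- rbind(head(pe, k), head(kw, k))
  rownames(out) <- NULL
  out
}

#' Feature importance by mean absolute attribution
#'
#' Per-feature additive attributions from the boosted trees (TreeSHAP
#' contract of the boosting library: per-prediction attributions plus the
#' base value sum to the model margin), summarised as the mean absolute
#' attribution over the supplied rows and ranked descending.
#'
#' @param bundle a `fall_model`.
#' @param feature_rows data.frame matching the training manifest.
#' @param top_n rows of the ranked table to return.
#' @return data.frame with `feature`, `mean_abs_attribution`, `rank`; the
#'   full attribution matrix is attached as attribute `attributions`.
#' @export
feature_importance <- function(bundle, feature_rows, top_n = 20L) {
  stopifnot(inherits(bundle, "fall_model"))
  m <- as.matrix(feature_rows[, bundle$manifest, drop = FALSE])
  storage.mode(m) <- "double"
  contrib <- predict(bundle$booster, xgboost::xgb.DMatrix(m, nthread = 1),
                     predcontrib = TRUE)
  colnames(contrib) <- c(bundle$manifest, "BIAS")
  imp <- colMeans(abs(contrib[, bundle$manifest, drop = FALSE]))
  ord <- order(-imp)
  out <- data.frame(feature = names(imp)[ord], mean_abs_attribution = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  out <- head(out, top_n)
  attr(out, "attributions") <- contrib
  out
}
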