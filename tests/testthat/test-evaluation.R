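test_that("auroc equals exhaustive pair counting on small samples", {
  set.seed(9)
  for (i in 1:8) {
    n <- sample(8:30, 1)
    y <- sample(c(rep(1, 3), rep(0, n - 3)))
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(metric("auroc", y, p), auroc_bruteforce(y, p), label = paste("case", i))
  }
  # perfect separation and closed forms
  y <- c(1, 1, 0, 0); p <- c(0.9, 0.8, 0.3, 0.1)
  expect_equal(metric("auroc", y, p), 1)
  expect_equal(metric("auprc", y, p), 1)
  expect_equal(metric("brier", y, p), mean(c(0.01, 0.04, 0.09, 0.01)))
  # probabilities equal to the sample prevalence: Brier = prev * (1 - prev)
  y2 <- c(1, 0, 0, 0)
  expect_equal(metric("brier", y2, rep(0.25, 4)), 0.25 * 0.75)
})

test_that("auprc matches the non-interpolated step-curve area on a worked set", {
  y <- c(1, 0, 1, 0, 0, 1, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  # descending order: precisions at the three positives: 1/1, 2/3, 3/6
  want <- (1 / 3) * 1 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 6)
  expect_equal(metric("auprc", y, p), want, tolerance = 1e-12)
})

test_that("threshold metrics derive from the confusion matrix at the cutoff", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.6, 0.2, 0.7, 0.4, 0.3, 0.1, 0.05)
  cut <- 0.5
  # confusion at 0.5: TP = 2, FN = 1, FP = 1, TN = 4
  expect_equal(metric("accuracy", y, p, cut), 6 / 8)
  expect_equal(metric("ppv", y, p, cut), 2 / 3)
  expect_equal(metric("sensitivity", y, p, cut), 2 / 3)
  expect_equal(metric("specificity", y, p, cut), 4 / 5)
  expect_equal(metric("f1", y, p, cut), 2 * 2 / (2 * 2 + 1 + 1))
})

test_that("kruskal-wallis and dunn match the hand-worked rank computation", {
  vals <- c(1.1, 2.3, 3.1, 4.2, 5.5, 2.0, 4.1, 6.3, 7.2, 8.8, 5.0, 6.1, 7.9, 9.4, 10.2)
  grp <- rep(c("a", "b", "c"), each = 5)
  kw <- kruskal.test(split(vals, grp))
  expect_equal(unname(kw$statistic), 6.14, tolerance = 1e-9)
  dn <- dunn_test(vals, grp)
  # frozen from explicit rank-sum arithmetic (rank sums 22, 41, 57)
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], -1.343503, tolerance = 1e-6)
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "c"], -2.474874, tolerance = 1e-6)
  expect_equal(dn$z[dn$group1 == "b" & dn$group2 == "c"], -1.131371, tolerance = 1e-6)
  expect_equal(dn$p_adjusted,
               c(0.537328, 0.039985, 0.773697), tolerance = 1e-5)
})

test_that("dunn tie correction matches kruskal.test's on tied data", {
  vals <- c(1, 2, 2, 3, 4, 2, 5, 5, 6, 7, 8, 8, 9, 1, 3)
  grp <- rep(c("a", "b", "c"), each = 5)
  dn <- dunn_test(vals, grp)
  expect_true(all(is.finite(dn$z)))
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted - 1e-12))
  expect_true(all(dn$p_adjusted <= 1))
})

test_that("paired bootstrap: shared indices, percentile CIs, degenerate cases", {
  set.seed(15)
  n <- 60
  y <- rep(c(1L, 0L), c(15, 45))
  p1 <- plogis(y * 2 - 1 + rnorm(n))
  probs <- list(m1 = p1, m2 = p1, m3 = p1)  # identical models
  bt <- bootstrap_compare(probs, y, n_boot = 200, seed = 3)
  # identical models: identical distributions, Kruskal-Wallis p = 1
  expect_equal(bt$distributions$auroc[, "m1"], bt$distributions$auroc[, "m2"])
  expect_equal(bt$tests$auroc$kruskal_p, 1, tolerance = 1e-9)
  expect_true(all(bt$tests$auroc$dunn$stars == ""))
  s <- bt$summary
  expect_true(all(s$ci_low <= s$ci_high))
  expect_true(all(s$point[s$metric == "auroc"] ==
                    metric("auroc", y, p1)))
  # constant metric across iterations: zero-width CI
  const <- bootstrap_compare(list(m = rep(0.5, n)), y,
                             metrics = "brier", n_boot = 50, seed = 1)
  expect_equal(const$summary$ci_low, const$summary$ci_high)
  expect_error(bootstrap_compare(probs, y, n_boot = 1), "n_boot")
})

test_that("bootstrap distinguishes genuinely different models with stars", {
  set.seed(16)
  n <- 120
  y <- rep(c(1L, 0L), each = n / 2)
  good <- plogis(3 * (y - 0.5) + rnorm(n, sd = 0.8))
  bad <- runif(n)
  bt <- bootstrap_compare(list(good = good, bad = bad), y,
                          metrics = "auroc", n_boot = 300, seed = 2)
  expect_lt(bt$tests$auroc$kruskal_p, 0.001)
  expect_equal(bt$tests$auroc$dunn$stars[1], "***")
})

test_that("net benefit equals brute-force confusion arithmetic and honours limits", {
  set.seed(19)
  y <- rbinom(50, 1, 0.3)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  p <- runif(50)
  dc <- decision_curve(y, list(m = p), thresholds = seq(0.05, 0.95, by = 0.05))
  m_rows <- dc[dc$model == "m", ]
  for (i in seq_len(nrow(m_rows)))
    expect_equal(m_rows$net_benefit[i],
                 net_benefit_bruteforce(y, p, m_rows$threshold[i]), tolerance = 1e-12)
  prev <- mean(y)
  expect_true(all(dc$net_benefit[dc$model == "treat_none"] == 0))
  ta <- dc[dc$model == "treat_all", ]
  expect_equal(ta$net_benefit[ta$threshold == 0.05],
               prev - (1 - prev) * 0.05 / 0.95)
  expect_true(all(m_rows$net_benefit <= prev + 1e-12))
  # worked example: prevalence 0.2, threshold 0.1, everyone called positive
  y2 <- rep(c(1, 0), c(10, 40))
  dc2 <- decision_curve(y2, list(m = rep(0.99, 50)), thresholds = 0.1)
  expect_equal(dc2$net_benefit[dc2$model == "m"], 0.2 - 0.8 / 9, tolerance = 1e-12)
  # thresholds outside (0,1) are dropped
  expect_equal(sort(unique(decision_curve(y2, list(m = rep(0.9, 50)),
                                          thresholds = c(0, 0.5, 1))$threshold)), 0.5)
})

test_that("delong test agrees with itself, the AUROC estimator and pROC", {
  set.seed(21)
  n <- 80
  y <- rep(c(1L, 0L), each = n / 2)
  pa <- plogis(2 * (y - 0.5) + rnorm(n))
  pb <- plogis(0.5 * (y - 0.5) + rnorm(n))
  expect_warning(same <- delong_test(y, pa, pa), "zero variance")
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  dl <- delong_test(y, pa, pb)
  expect_equal(dl$auroc_a, metric("auroc", y, pa))
  expect_equal(dl$auroc_b, metric("auroc", y, pb))
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, pa, quiet = TRUE),
                        pROC::roc(y, pb, quiet = TRUE), method = "delong")
  expect_equal(dl$p, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(abs(dl$z), abs(unname(ref$statistic)), tolerance = 1e-8)
})

test_that("subgroup analysis partitions the test set and is null under coin flips", {
  set.seed(23)
  n <- 300
  y <- rbinom(n, 1, 0.25)
  p <- plogis(2 * (y - 0.5) + rnorm(n))
  ps <- 0
  for (s in 1:10) {
    strata <- data.frame(coin = sample(c("h", "t"), n, replace = TRUE))
    res <- subgroup_auroc(p, y, strata)
    expect_equal(res$n1 + res$n2, n)
    if (!is.na(res$p) && res$p > 0.05) ps <- ps + 1
  }
  expect_gte(ps, 9)
  # age boundary: a 65-year-old lands in the lower stratum
  ax <- subgroup_axes(data.frame(age = c(65, 66), sex = c(1, 0), los = c(7, 8)))
  expect_equal(ax$age_group, c("age<=65", "age>65"))
  expect_equal(ax$los_group, c("los<=7", "los>7"))
})

test_that("baseline table gates tests on normality and matches the classic chi-square", {
  set.seed(25)
  n <- 600
  y <- rep(c(1L, 0L), c(150, 450))
  tab <- data.frame(
    normal_shift = rnorm(n, ifelse(y == 1, 2, 0), 1),
    skewed = rlnorm(n, 0, 1),
    exposure = rbinom(n, 1, ifelse(y == 1, 0.4, 0.2)))
  bt <- baseline_table(tab, y)
  expect_equal(bt$test[bt$variable == "normal_shift"], "t-test")
  expect_lt(bt$p[bt$variable == "normal_shift"], 0.001)
  expect_equal(bt$test[bt$variable == "skewed"], "mann-whitney")
  expect_equal(bt$test[bt$variable == "exposure"], "chi-square")

  # 2x2 chi-square equals the classic closed-form n(ad-bc)^2/(row x col products)
  sex <- rep(c("male", "female", "male", "female"), c(77, 41, 218, 225))
  grp <- rep(c(1L, 0L), c(118, 443))
  bt2 <- baseline_table(data.frame(sex = sex), grp)
  a <- 77; b <- 41; c <- 218; d <- 225; N <- a + b + c + d
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(bt2$p, pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_lt(bt2$p, 0.01)

  # identical groups: p spread over (0,1), no systematic significance
  null_p <- replicate(10, {
    x <- rnorm(n)
    baseline_table(data.frame(v = x), sample(y))$p
  })
  expect_gt(mean(null_p > 0.05), 0.7)
})

test_that("association screen ranks pearson and kruskal families and handles self-pairs", {
  set.seed(27)
  n <- 500
  clin <- data.frame(age = rnorm(n, 70, 10),
                     dept = sample(c("medicine", "surgery"), n, TRUE))
  rtls <- data.frame(speed = rnorm(n), dist = rnorm(n))
  rtls$linked <- -0.5 * clin$age + rnorm(n, sd = 3)
  res <- association_screen(clin, rtls, k = 2)
  expect_true(all(res$test %in% c("pearson", "kruskal-wallis")))
  pe <- res[res$test == "pearson", ]
  expect_equal(pe$rtls[1], "linked")  # strongest |r| ranked first
  # self-pair sanity: a feature screened against a copy of itself has r = 1
  self <- association_screen(data.frame(x = 1:50), data.frame(y = 1:50), k = 1)
  expect_equal(self$statistic[1], 1)
  # independent columns stay weak in most seeds
  weak <- replicate(10, {
    r <- association_screen(data.frame(a = rnorm(n)), data.frame(b = rnorm(n)), k = 1)
    abs(r$statistic[1]) < 0.15
  })
  expect_gte(sum(weak), 9)
  # k larger than the pair count returns everything
  all_pairs <- association_screen(clin["age"], rtls, k = 99)
  expect_equal(nrow(all_pairs), 3)
})

test_that("feature attributions satisfy additivity and rank informative features", {
  set.seed(29)
  x <- data.frame(signal = rnorm(150), noise1 = rnorm(150), noise2 = rnorm(150))
  y <- as.integer(x$signal + rnorm(150, sd = 0.4) > 0)
  b <- train_model(x, y, "clinical", grid = small_grid(), folds = 5, seed = 1)
  imp <- feature_importance(b, x)
  expect_equal(imp$feature[1], "signal")
  contrib <- attr(imp, "attributions")
  m <- as.matrix(x); storage.mode(m) <- "double"
  margin <- predict(b$booster, xgboost::xgb.DMatrix(m, nthread = 1),
                    outputmargin = TRUE)
  expect_equal(unname(rowSums(contrib)), margin, tolerance = 1e-4)
})
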