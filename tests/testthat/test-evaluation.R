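test_that("confusion counting follows the inclusive threshold convention", {
  # -1 is below (more damaging than) -0.75, so both positives are called
  cc <- confusionFromPredictions(c(-2, -1, 0, 1), c("P", "P", "N", "N"), -0.75)
  expect_equal(counts(cc), c(tp = 2, fp = 0, tn = 2, fn = 0))
  cc2 <- confusionFromPredictions(rep(-10, 5), rep("CANCER", 5) , -0.75)
  expect_equal(counts(cc2)[["tp"]], 5)
  # a threshold above every score calls everything positive
  cc3 <- confusionFromPredictions(c(-1, 0, 1), c(1, 0, 0), 100)
  expect_equal(counts(cc3), c(tp = 1, fp = 2, tn = 0, fn = 0))
  expect_error(confusionFromPredictions(1:3, 1:2, 0), "equal length")
})

test_that("confusion counting matches per-item brute force on random tables", {
  set.seed(41)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    scores <- round(stats::rnorm(n), 2)
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    tau <- round(stats::rnorm(1), 2)
    expect_equal(counts(confusionFromPredictions(scores, pos, tau)),
                 bruteConfusion(scores, pos, tau))
  }
})

test_that("degenerate metric cases behave", {
  perfect <- computeMetrics(new("ConfusionCounts", tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unname(metricValues(perfect)), rep(1, 6))
  chance <- computeMetrics(new("ConfusionCounts", tp = 10, fp = 10, tn = 10, fn = 10))
  expect_equal(chance@sensitivity, 0.5)
  expect_equal(chance@specificity, 0.5)
  expect_equal(chance@mcc, 0)
  # normalized accuracy is always the mean of sensitivity and specificity
  set.seed(59)
  for (i in 1:50) {
    v <- sample(1:500, 4, replace = TRUE)
    ms <- computeMetrics(new("ConfusionCounts", tp = v[1], fp = v[2],
                             tn = v[3], fn = v[4]))
    expect_equal(ms@accuracy, (ms@sensitivity + ms@specificity) / 2,
                 tolerance = 1e-12)
  }
})

test_that("raw and normalized metrics agree on balanced classes", {
  set.seed(61)
  for (i in 1:100) {
    n_pos <- sample(10:400, 1)
    tp <- sample(0:n_pos, 1); fn <- n_pos - tp
    fp <- sample(0:n_pos, 1); tn <- n_pos - fp
    if (tp + fp == 0 || tn + fn == 0) next
    cc <- new("ConfusionCounts", tp = tp, fp = fp, tn = tn, fn = fn)
    expect_equal(metricValues(computeMetrics(cc, normalized = TRUE)),
                 metricValues(computeMetrics(cc, normalized = FALSE)),
                 tolerance = 1e-12)
  }
})

test_that("undefined metrics surface as NA markers", {
  # nothing called positive: precision undefined under raw counting
  ms <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, tn = 5, fn = 5),
                       normalized = FALSE)
  expect_true(is.na(ms@precision))
  expect_error(computeMetrics(new("ConfusionCounts", tp = 0, fp = 3, tn = 2, fn = 0)),
               "each class")
})

test_that("cumulative ROC handles separation, ties and truncation", {
  # perfectly separated: full positive count before any false positive
  roc <- cumulativeROC(c(-5, -4, -3, 1, 2), c(1, 1, 1, 0, 0))
  pts <- rocPoints(roc)
  expect_equal(pts$cum_tp[pts$cum_fp == 0][3], 3)
  expect_equal(unlist(pts[nrow(pts), c("cum_fp", "cum_tp")], use.names = FALSE),
               c(2, 3))
  # all scores identical: a single tie block
  roc2 <- cumulativeROC(rep(1, 6), c(1, 1, 0, 0, 0, 1))
  expect_equal(nrow(rocPoints(roc2)), 1L)
  expect_equal(unlist(rocPoints(roc2)[1, c("cum_fp", "cum_tp")],
                      use.names = FALSE), c(3, 3))
  # truncation at a false-positive fraction
  roc3 <- cumulativeROC(c(-3, -2, -1, 0, 1, 2), c(1, 1, 0, 1, 0, 0),
                        fp_fraction_cap = 1 / 3)
  expect_true(all(rocPoints(roc3)$cum_fp <= 1))
  expect_error(cumulativeROC(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("the ROC curve equals a brute-force threshold sweep", {
  set.seed(71)
  scores <- round(c(stats::rnorm(100, -1), stats::rnorm(100, 1)), 1)
  pos <- rep(c(TRUE, FALSE), each = 100)
  pts <- rocPoints(cumulativeROC(scores, pos))
  expect_equal(pts, bruteROC(scores, pos), ignore_attr = TRUE)
})

test_that("trapezoidal ROC area equals Mann-Whitney concordance", {
  set.seed(73)
  for (rep in 1:5) {
    n <- sample(c(50, 200, 500), 1)
    scores <- round(stats::rnorm(n, ifelse(stats::runif(n) < 0.4, -1.5, 0.5)), 1)
    pos <- scores + stats::rnorm(n) < 0
    if (!any(pos) || all(pos)) next
    auc <- rocArea(cumulativeROC(scores, pos))
    expect_equal(auc, bruteConcordance(scores, pos), tolerance = 1e-12)
  }
})

test_that("ROC area agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(107)
  scores <- round(c(stats::rnorm(80, -1), stats::rnorm(80, 0.6)), 1)
  pos <- rep(c(1, 0), each = 80)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, direction = ">",
                                        levels = c(0, 1), quiet = TRUE)))
  expect_equal(rocArea(cumulativeROC(scores, pos)), ref, tolerance = 1e-12)
})

test_that("threshold derivation lands in a planted separable gap", {
  set.seed(79)
  d <- data.frame(score = c(stats::runif(40, -5, -2), stats::runif(40, 0, 3)),
                  label = rep(c(1, 0), each = 40))
  tau <- deriveThreshold(list(d))
  expect_gt(tau, -2)
  expect_lt(tau, 0)
})

test_that("threshold derivation maximizes the summed objective over the grid", {
  set.seed(83)
  dA <- data.frame(score = c(stats::rnorm(60, -1.6, 0.4), stats::rnorm(60, -0.4, 0.4)),
                   label = rep(c(1, 0), each = 60))
  dB <- data.frame(score = c(stats::rnorm(60, -1.0, 0.4), stats::rnorm(60, 0.2, 0.4)),
                   label = rep(c(1, 0), each = 60))
  tau <- deriveThreshold(list(dA, dB))
  grid <- seq(floor(min(c(dA$score, dB$score)) / 0.05) * 0.05,
              ceiling(max(c(dA$score, dB$score)) / 0.05) * 0.05, by = 0.05)
  objs <- vapply(grid, function(t) bruteThresholdObjective(list(dA, dB), t),
                 numeric(1))
  expect_equal(bruteThresholdObjective(list(dA, dB), tau), max(objs),
               tolerance = 1e-12)
  # invariant to dataset order
  expect_equal(deriveThreshold(list(dB, dA)), tau)
  expect_error(deriveThreshold(list()), "no datasets")
})

test_that("odds ratios match the closed form with a zero-cell correction", {
  expect_equal(oddsRatio(10, 10, 10, 10)$or, 1)
  or <- oddsRatio(20, 5, 10, 10)
  expect_equal(or$or, 4)
  expect_equal(or$ci_low, exp(log(4) - 1.96 * sqrt(1/20 + 1/5 + 1/10 + 1/10)),
               tolerance = 1e-10)
  expect_equal(or$ci_high, exp(log(4) + 1.96 * sqrt(1/20 + 1/5 + 1/10 + 1/10)),
               tolerance = 1e-10)
  expect_false(or$corrected)
  # doubling all counts preserves the OR and narrows the interval
  or2 <- oddsRatio(40, 10, 20, 20)
  expect_equal(or2$or, 4)
  expect_lt(or2$ci_high - or2$ci_low, or$ci_high - or$ci_low)
  # zero cell triggers the Haldane-Anscombe correction
  orz <- oddsRatio(10, 0, 5, 5)
  expect_true(orz$corrected)
  expect_true(is.finite(orz$or))
})

test_that("cross-validation folds are stratified, seeded and order-stable", {
  b <- generateScenario(smallScenario(seed = 43, n_per_class = 60))
  cv <- kfoldWeightsCV(b$variants, b$assignments, b$models, k = 4, seed = 9)
  preds <- cv$predictions
  expect_equal(sort(unique(preds$fold)), 1:4)
  for (f in 1:4)
    expect_true(all(c("CANCER", "NEUTRAL") %in% preds$label[preds$fold == f]))
  # shuffling the input leaves fold membership of each variant unchanged
  shuffle <- sample(nrow(b$variants))
  cv2 <- kfoldWeightsCV(b$variants[shuffle, ], b$assignments, b$models,
                        k = 4, seed = 9)
  key <- function(p) paste(p$protein_id, p$position, p$wild_type, p$mutant)
  m <- match(key(preds), key(cv2$predictions))
  expect_equal(cv2$predictions$fold[m], preds$fold)
  expect_equal(cv2$predictions$score[m], preds$score)
})

test_that("leave-one-out scores each variant against a table excluding itself", {
  b <- generateScenario(smallScenario(seed = 47, n_per_class = 15))
  n <- nrow(b$variants)
  cv <- kfoldWeightsCV(b$variants, b$assignments, b$models, k = n, seed = 1)
  preds <- cv$predictions
  expect_equal(length(unique(preds$fold)), n)
  expect_true(all(!is.na(preds$score)))
  # spot-check: the held-out score is computed from the complement's table
  mapped <- assignVariantsToModels(b$variants, b$assignments, b$models)
  cfg <- classifierConfig()
  i <- 1L
  wt_i <- computeWeightTable(mapped[-i, , drop = FALSE])
  em <- emissions(b$models[[mapped$model_id[i]]])[mapped$match_state[i], ]
  w <- weightsFor(wt_i, mapped$model_id[i])
  expect_equal(preds$score[preds$fold == preds$fold[i]][1],
               weightedScore(em[[mapped$wild_type[i]]], em[[mapped$mutant[i]]],
                             w[["w_c"]], w[["w_p"]]))
})
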