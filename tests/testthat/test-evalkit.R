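test_that("Dice coefficient covers the full overlap spectrum", {
  a <- matrix(0, 10, 10); a[1:5, ] <- 1
  expect_identical(diceCoefficient(a, a), 1)
  b <- matrix(0, 10, 10); b[6:10, ] <- 1
  expect_identical(diceCoefficient(a, b), 0)
  m <- matrix(0, 20, 20); m[1:10, 1:10] <- 1
  g <- matrix(0, 20, 20); g[6:15, 1:10] <- 1
  expect_identical(diceCoefficient(m, g), 0.5)
  expect_identical(diceCoefficient(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_error(diceCoefficient(a, matrix(0, 4, 4)), "identical dimensions")
})

test_that("confusion counts match exhaustive tallies on random vectors", {
  expect_identical(confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                   list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  p <- c(1, 1, 0, 0); l <- 1 - p
  cc <- confusionCounts(p, l)
  expect_identical(cc$TP, 0L); expect_identical(cc$TN, 0L)
  set.seed(21)
  for (i in 1:10) {
    preds <- rbinom(20, 1, 0.5); labels <- rbinom(20, 1, 0.5)
    got <- confusionCounts(preds, labels)
    oracle <- bfConfusion(preds, labels)
    expect_equal(got[c("TP", "FP", "TN", "FN")],
                 oracle[c("TP", "FP", "TN", "FN")], ignore_attr = TRUE)
    expect_identical(got$TP + got$FP + got$TN + got$FN, 20L)
  }
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
  expect_error(confusionCounts(c(2, 0), c(1, 0)), "0/1")
})

test_that("classification metrics follow their closed forms", {
  m <- classificationMetrics(list(TP = 8, FN = 2, FP = 3, TN = 7))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1, 16 / 21)
  perfect <- classificationMetrics(list(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_true(all(unlist(perfect) == 1))
  worst <- suppressWarnings(classificationMetrics(list(TP = 0, FN = 4, FP = 4, TN = 0)))
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$f1, 0)
  expect_warning(classificationMetrics(list(TP = 0, FN = 0, FP = 2, TN = 2)),
                 "sensitivity undefined")
  expect_error(classificationMetrics(list(TP = -1, FN = 0, FP = 0, TN = 1)),
               "non-negative")
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(22)
  for (i in 1:25) {
    c <- as.list(setNames(rmultinom(1, 40, rep(0.25, 4))[, 1],
                          c("TP", "FP", "TN", "FN")))
    m <- suppressWarnings(classificationMetrics(c))
    pos <- c$TP + c$FN; neg <- c$TN + c$FP
    if (pos == 0 || neg == 0) next
    expect_equal(m$accuracy,
                 (pos * m$sensitivity + neg * m$specificity) / (pos + neg))
  }
})

test_that("subject-wise folds partition subjects with no leakage", {
  ids <- sprintf("s%02d", 1:10)
  fa <- nestedCVSplit(ids, k = 5, innerK = 3, seed = 4)
  expect_identical(lengths(fa$outer_folds), rep(2L, 5))
  expect_setequal(unlist(fa$outer_folds), ids)
  expect_identical(anyDuplicated(unlist(fa$outer_folds)), 0L)
  for (i in 1:5) {
    train <- unlist(fa$inner_folds[[i]])
    expect_setequal(train, setdiff(ids, fa$outer_folds[[i]]))
  }
  expect_identical(nestedCVSplit(ids, seed = 4), fa)
  expect_false(identical(nestedCVSplit(ids, seed = 5)$outer_folds, fa$outer_folds))
  expect_error(nestedCVSplit(sprintf("s%d", 1:4), k = 5), "at least k")
})

test_that("all images of a subject land on the same side of every split", {
  images <- data.frame(subject = rep(sprintf("s%02d", 1:8), times = 2),
                       image = sprintf("i%02d", 1:16))
  fa <- nestedCVSplit(unique(images$subject), k = 4, seed = 2)
  for (i in seq_along(fa$outer_folds)) {
    inTest <- images$subject %in% fa$outer_folds[[i]]
    split <- tapply(inTest, images$subject, function(x) length(unique(x)))
    expect_true(all(split == 1))
  }
})

test_that("activity requires at least three of five criteria and is monotone", {
  lab <- function(...) setNames(c(...), octaFeatures())
  expect_true(activityScore(lab(1, 1, 1, 0, 0))$active)
  expect_identical(activityScore(lab(1, 1, 1, 0, 0))$criteria_count, 3L)
  expect_false(activityScore(lab(1, 1, 0, 0, 0))$active)
  expect_true(activityScore(lab(1, 1, 1, 1, 1))$active)
  expect_identical(activityScore(lab(1, 1, 1, 1, 1))$criteria_count, 5L)
  expect_error(activityScore(c(branch = 1)), "missing criterion")
  # monotonicity over all 32 label combinations
  combos <- expand.grid(rep(list(0:1), 5))
  names(combos) <- octaFeatures()
  for (r in seq_len(nrow(combos))) {
    base <- activityScore(combos[r, ])
    for (f in octaFeatures()) {
      if (combos[r, f] == 1) next
      up <- combos[r, ]; up[f] <- 1
      if (base$active) expect_true(activityScore(up)$active)
    }
  }
})

test_that("prevalence percentages use half-up rounding to two decimals", {
  mk <- function(counts, total) {
    df <- as.data.frame(lapply(setNames(counts, octaFeatures()), function(k)
      rep(c(1, 0), c(k, total - k))))
    df
  }
  tab <- prevalenceSummary(mk(c(68, 49, 63, 100, 62), 130))
  expect_identical(tab$percentage[tab$feature == "peripheral_arcade"], 76.92)
  expect_identical(tab$percentage[tab$feature == "dark_halo"], 47.69)
  expect_identical(tab$percentage[tab$feature == "shape"], 37.69)
  # half-up: 100 * 68/130 = 52.3077 -> 52.31
  expect_identical(tab$percentage[tab$feature == "branch"], 52.31)
  zero <- prevalenceSummary(mk(rep(0, 5), 10))
  expect_true(all(zero$percentage == 0))
  expect_error(prevalenceSummary(data.frame()), "empty")
})

test_that("fold aggregation keeps the per-fold Dice distribution", {
  fd <- list(c(0.8, 0.9), c(0.7, 0.75, 0.85), c(1, 0.6))
  rep <- metricsReport(fd)
  expect_identical(rep$per_fold_dice, fd)
  expect_equal(rep$fold_dice_median, c(0.85, 0.75, 0.8))
  expect_equal(rep$overall_dice_mean, mean(unlist(fd)))
  expect_equal(rep$overall_dice_median, median(unlist(fd)))
})
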