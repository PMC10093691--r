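# Overlap metrics, confusion-matrix metrics, subject-wise nested
# cross-validation and the five-criteria activity score.

#' Dice similarity coefficient
#'
#' \code{2 * |pred & gt| / (|pred| + |gt|)}, i.e. \code{2TP / (2TP+FP+FN)}
#' on pixels; ranges from 0 (no spatial overlap) to 1 (complete overlap).
#' When both masks are empty the coefficient is defined as 1 (perfect
#' agreement on absence).
#'
#' @param pred,gt 0/1 matrices of equal shape.
#' @return Scalar in \code{[0,1]}.
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' diceCoefficient(a, a)
diceCoefficient <- function(pred, gt) {
  assertMask(pred, "pred"); assertMask(gt, "gt")
  assertSameShape(pred, gt)
  denom <- sum(pred) + sum(gt)
  if (denom == 0) return(1)
  2 * sum(pred * gt) / denom
}

#' Confusion counts for binary predictions
#'
#' Standard 2 x 2 tabulation with positive class 1.
#'
#' @param preds,labels 0/1 vectors of equal length.
#' @return Named list TP, FP, TN, FN (integers).
#' @export
confusionCounts <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("preds and labels differ in length")
  if (!all(preds %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("preds and labels must be 0/1")
  list(TP = sum(preds == 1 & labels == 1),
       FP = sum(preds == 1 & labels == 0),
       TN = sum(preds == 0 & labels == 0),
       FN = sum(preds == 0 & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+FP+FN+TN); F1 = 2TP/(2TP+FP+FN);
#' specificity = TN/(TN+FP); sensitivity = TP/(TP+FN). A metric whose
#' denominator is zero is reported as NaN with a warning (rather than a
#' silent zero, which would corrupt fold averages).
#'
#' @param counts list with TP, FP, TN, FN (non-negative).
#' @return Named list accuracy, f1, specificity, sensitivity.
#' @export
#' @examples
#' classificationMetrics(list(TP = 8, FN = 2, FP = 3, TN = 7))
classificationMetrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be non-negative")
    safe <- function(num, den, what) {
      if (den == 0) { warning(what, " undefined (zero denominator)"); return(NaN) }
      num / den
    }
    list(accuracy = safe(TP + TN, TP + FP + FN + TN, "accuracy"),
         f1 = safe(2 * TP, 2 * TP + FP + FN, "F1"),
         specificity = safe(TN, TN + FP, "specificity"),
         sensitivity = safe(TP, TP + FN, "sensitivity"))
  })
}

#' Subject-wise nested cross-validation folds
#'
#' Subjects are shuffled by the seed and partitioned into \code{k}
#' near-equal outer folds; all images of a subject follow their subject, so
#' no subject can appear on both sides of any split. Within each outer
#' training set, \code{innerK} validation folds are formed the same way for
#' hyperparameter selection.
#'
#' @param subjectIds character vector (one entry per subject; duplicates
#'   are collapsed).
#' @param k outer folds (default 5).
#' @param innerK inner folds per outer training set.
#' @param seed shuffle seed.
#' @return Object of class \code{foldAssignment}: list with
#'   \code{outer_folds} (k character vectors of held-out subjects),
#'   \code{inner_folds} (per outer fold, innerK vectors), \code{seed}.
#' @export
nestedCVSplit <- function(subjectIds, k = 5L, innerK = 3L, seed = 1L) {
  subjects <- unique(as.character(subjectIds))
  if (length(subjects) < k)
    stop("need at least k = ", k, " distinct subjects, got ", length(subjects))
  partition <- function(x, m) {
    split(x, rep(seq_len(m), length.out = length(x)))
  }
  withSeed(seed, {
    outer <- partition(sample(subjects), k)
    inner <- lapply(seq_len(k), function(i) {
      train <- setdiff(subjects, outer[[i]])
      partition(sample(train), min(innerK, length(train)))
    })
    structure(list(outer_folds = unname(outer),
                   inner_folds = lapply(inner, unname),
                   k = as.integer(k), inner_k = as.integer(innerK),
                   seed = as.integer(seed)),
              class = "foldAssignment")
  })
}

#' @export
print.foldAssignment <- function(x, ...) {
  cat(sprintf("Subject-wise nested CV: %d outer folds x %d inner, seed %d\n",
              x$k, x$inner_k, x$seed))
  for (i in seq_len(x$k))
    cat(sprintf("  fold %d: %d test subject(s)\n", i, length(x$outer_folds[[i]])))
  invisible(x)
}

#' CNV activity score
#'
#' A lesion is graded active when at least three of the five activity
#' criteria are present. Monotone: turning any criterion on never
#' deactivates a lesion.
#'
#' @param labels named 0/1 vector (or list) covering \code{octaFeatures()}.
#' @return list(active = logical, criteria_count = integer).
#' @export
#' @examples
#' activityScore(c(branch = 1, shape = 1, anastomosis_loops = 1,
#'                 peripheral_arcade = 0, dark_halo = 0))
activityScore <- function(labels) {
  labels <- unlist(labels)
  missing <- setdiff(OCTA_FEATURES, names(labels))
  if (length(missing)) stop("missing criterion label(s): ",
                            paste(missing, collapse = ", "))
  v <- labels[OCTA_FEATURES]
  if (anyNA(v) || !all(v %in% c(0, 1))) stop("labels must be 0/1 for all five criteria")
  n <- sum(v)
  list(active = n >= 3, criteria_count = as.integer(n))
}

#' Per-feature label prevalence summary
#'
#' Presence counts and percentages (half-up rounding to two decimals) per
#' activity criterion, as printed in cohort summary tables.
#'
#' @param labelTable data.frame containing the five criterion columns.
#' @return data.frame with feature, count, total, percentage.
#' @export
#' @examples
#' df <- data.frame(branch = c(1, 0), shape = c(1, 1),
#'                  anastomosis_loops = 0, peripheral_arcade = 1,
#'                  dark_halo = c(0, 1))
#' prevalenceSummary(df)
prevalenceSummary <- function(labelTable) {
  if (!nrow(labelTable)) stop("label table is empty")
  missing <- setdiff(OCTA_FEATURES, names(labelTable))
  if (length(missing)) stop("label table misses column(s): ",
                            paste(missing, collapse = ", "))
  total <- nrow(labelTable)
  data.frame(feature = OCTA_FEATURES,
             count = vapply(OCTA_FEATURES, function(f) sum(labelTable[[f]]),
                            numeric(1)),
             total = total,
             percentage = vapply(OCTA_FEATURES, function(f)
               roundHalfUp(100 * sum(labelTable[[f]]) / total, 2), numeric(1)),
             row.names = NULL)
}

#' Aggregate per-fold results into a metrics report
#'
#' Keeps the per-fold Dice distribution (with fold medians and the overall
#' median, suitable for violin-style reporting) and averages the per-feature
#' classification metrics across folds with equal fold weight.
#'
#' @param foldDice list of numeric vectors, per-image Dice per outer fold.
#' @param foldFeatureMetrics list (per fold) of lists (per feature) of
#'   metric lists as returned by \code{\link{classificationMetrics}}.
#' @return Object of class \code{metricsReport}.
#' @export
metricsReport <- function(foldDice, foldFeatureMetrics = NULL) {
  rep <- list(
    per_fold_dice = foldDice,
    fold_dice_mean = vapply(foldDice, mean, numeric(1)),
    fold_dice_median = vapply(foldDice, median, numeric(1)),
    overall_dice_mean = mean(unlist(foldDice)),
    overall_dice_median = median(unlist(foldDice)))
  if (!is.null(foldFeatureMetrics)) {
    feats <- names(foldFeatureMetrics[[1]])
    rep$per_feature <- lapply(setNames(feats, feats), function(f) {
      ms <- lapply(foldFeatureMetrics, `[[`, f)
      lapply(setNames(c("accuracy", "f1", "specificity", "sensitivity"),
                      c("accuracy", "f1", "specificity", "sensitivity")),
             function(m) mean(vapply(ms, `[[`, numeric(1), m), na.rm = TRUE))
    })
  }
  structure(rep, class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat(sprintf("Dice: mean %.3f, median %.3f over %d folds (fold means: %s)\n",
              x$overall_dice_mean, x$overall_dice_median,
              length(x$per_fold_dice),
              paste(sprintf("%.3f", x$fold_dice_mean), collapse = ", ")))
  if (!is.null(x$per_feature)) {
    for (f in names(x$per_feature)) {
      m <- x$per_feature[[f]]
      cat(sprintf("  %-18s acc %.3f  f1 %.3f  spec %.3f  sens %.3f\n", f,
                  m$accuracy, m$f1, m$specificity, m$sensitivity))
    }
  }
  invisible(x)
}
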