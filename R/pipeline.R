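# End-to-end orchestration: segmentation block -> classification block ->
# activity score, evaluated under subject-wise nested cross-validation.

#' Pipeline configuration
#'
#' Problem-size and training knobs for \code{\link{runPipeline}}. One global
#' seed governs every stochastic stage (fold shuffling, weight inits,
#' training).
#'
#' @param k,innerK outer/inner folds (subject-wise).
#' @param segSize SEG-CNV input side (divisible by 16).
#' @param segEpochs,segBatch,segLr SEG-CNV training settings.
#' @param headSize transfer-head input side (divisible by 32).
#' @param scratchSize scratch-net input side (divisible by 16).
#' @param headEpochs,headBatch classifier training settings.
#' @param augment use augmentation during training.
#' @param morpho parameters from \code{\link{morphoParams}}.
#' @param seed global seed.
#' @return Named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(k = 5L, innerK = 3L, segSize = 64L, segEpochs = 12L,
                           segBatch = 8L, segLr = 1e-3, headSize = 32L,
                           scratchSize = 64L, headEpochs = 10L, headBatch = 8L,
                           augment = FALSE, morpho = morphoParams(),
                           seed = 1L) {
  structure(list(k = as.integer(k), innerK = as.integer(innerK),
                 segSize = as.integer(segSize), segEpochs = as.integer(segEpochs),
                 segBatch = as.integer(segBatch), segLr = segLr,
                 headSize = as.integer(headSize),
                 scratchSize = as.integer(scratchSize),
                 headEpochs = as.integer(headEpochs),
                 headBatch = as.integer(headBatch), augment = isTRUE(augment),
                 morpho = morpho, seed = as.integer(seed)),
            class = "pipelineConfig")
}

# Segmentation block for one sample given a trained seg model: CNV mask,
# ROI, PA mask, DH mask.
segmentationBlock <- function(segModel, sample, morpho = morphoParams()) {
  outer <- outerRetina(sample); choroid <- choriocapillaris(sample)
  mask <- predictMask(segModel, outer)
  roi <- makeROI(outer, mask)
  if (sum(mask) == 0) {
    pa <- mask; dh <- mask
  } else {
    pa <- segPA(outer, mask, morpho)
    dh <- segDH(choroid, mask, morpho)
  }
  list(mask = mask, roi = roi, pa = pa, dh = dh)
}

constantHead <- function(feature, label) {
  structure(list(constant = as.integer(label), spec = list(feature = feature)),
            class = "constantHead")
}

headPredict <- function(model, image) {
  if (inherits(model, "constantHead"))
    list(feature = model$spec$feature, probability = as.numeric(model$constant),
         label = model$constant)
  else predictFeature(model, image)
}

#' Run the full two-stage pipeline under nested cross-validation
#'
#' For each outer fold: trains SEG-CNV on the training subjects' outer-retina
#' images, derives the CNV ROI / peripheral-arcade / dark-halo inputs for
#' every sample from the predicted masks, trains the five criterion heads on
#' the training side, then predicts the five labels and the activity score
#' for the held-out subjects. A training fold in which some criterion has a
#' single class yields a constant (majority) classifier for that criterion.
#'
#' @param samples list of \linkS4class{PhantomSample} (e.g. from
#'   \code{\link{generatePhantomDataset}} or \code{\link{loadManifestSamples}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory for the report, predictions CSV and
#'   reproducibility record.
#' @return list with \code{report} (a \code{metricsReport}), \code{predictions}
#'   (data.frame: ids, per-feature probability/label, truth, activity),
#'   \code{folds} (the \code{foldAssignment}).
#' @export
runPipeline <- function(samples, config = pipelineConfig(), outDir = NULL) {
  subjects <- vapply(samples, subjectId, character(1))
  folds <- nestedCVSplit(unique(subjects), k = config$k, innerK = config$innerK,
                         seed = config$seed)
  feats <- octaFeatures()
  foldDice <- vector("list", config$k)
  foldMetrics <- vector("list", config$k)
  predRows <- list()

  for (fi in seq_len(config$k)) {
    testSubj <- folds$outer_folds[[fi]]
    isTest <- subjects %in% testSubj
    trainS <- samples[!isTest]; testS <- samples[isTest]

    seg <- buildSegCNV(config$segSize, config$segSize, seed = config$seed + fi)
    seg <- trainSegCNV(seg, trainS,
                       segTrainConfig(epochs = config$segEpochs,
                                      batch = config$segBatch, lr = config$segLr,
                                      seed = config$seed + fi,
                                      augment = config$augment))$model

    blocksTrain <- lapply(trainS, function(s) segmentationBlock(seg, s, config$morpho))
    blocksTest <- lapply(testS, function(s) segmentationBlock(seg, s, config$morpho))
    foldDice[[fi]] <- vapply(seq_along(testS), function(i)
      diceCoefficient(blocksTest[[i]]$mask, cnvMask(testS[[i]])), numeric(1))

    heads <- list()
    for (f in feats) {
      labs <- vapply(trainS, function(s) activityLabels(s)[[f]], integer(1))
      tr <- lapply(seq_along(trainS), function(i)
        list(image = routeInput(f, blocksTrain[[i]]$roi, blocksTrain[[i]]$pa,
                                blocksTrain[[i]]$dh),
             label = labs[i]))
      if (length(unique(labs)) < 2) {
        heads[[f]] <- constantHead(f, round(mean(labs)))
        next
      }
      m <- if (f == "peripheral_arcade")
        buildScratchNet(config$scratchSize, seed = config$seed + fi)
      else buildTransferHead(f, inputSize = config$headSize,
                             seed = config$seed + fi)
      heads[[f]] <- trainHead(m, tr,
                              headTrainConfig(epochs = config$headEpochs,
                                              batch = config$headBatch,
                                              seed = config$seed + fi,
                                              augment = config$augment))$model
    }

    featPreds <- lapply(setNames(feats, feats), function(f)
      lapply(seq_along(testS), function(i)
        headPredict(heads[[f]],
                    routeInput(f, blocksTest[[i]]$roi, blocksTest[[i]]$pa,
                               blocksTest[[i]]$dh))))
    foldMetrics[[fi]] <- lapply(setNames(feats, feats), function(f) {
      preds <- vapply(featPreds[[f]], `[[`, integer(1), "label")
      truth <- vapply(testS, function(s) activityLabels(s)[[f]], integer(1))
      suppressWarnings(classificationMetrics(confusionCounts(preds, truth)))
    })

    for (i in seq_along(testS)) {
      lab <- setNames(vapply(feats, function(f) featPreds[[f]][[i]]$label,
                             integer(1)), feats)
      sc <- activityScore(lab)
      truth <- activityLabels(testS[[i]])
      row <- data.frame(fold = fi, subject_id = subjectId(testS[[i]]),
                        image_id = imageId(testS[[i]]),
                        dice = foldDice[[fi]][i])
      for (f in feats) {
        row[[paste0(f, "_prob")]] <- featPreds[[f]][[i]]$probability
        row[[paste0(f, "_pred")]] <- lab[[f]]
        row[[paste0(f, "_true")]] <- truth[[f]]
      }
      row$criteria_count <- sc$criteria_count
      row$active <- sc$active
      row$active_true <- activityScore(truth)$active
      predRows[[length(predRows) + 1]] <- row
    }
  }

  predictions <- do.call(rbind, predRows)
  report <- metricsReport(foldDice, foldMetrics)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(predictions, file.path(outDir, "predictions.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(report = unclass(report),
           record = list(config = unclass(config), seed = config$seed,
                         package_version = as.character(utils::packageVersion("octacnv")))),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    diceDf <- do.call(rbind, lapply(seq_along(foldDice), function(i)
      data.frame(fold = i, dice = foldDice[[i]])))
    write.csv(diceDf, file.path(outDir, "fold_dice.csv"), row.names = FALSE)
  }
  list(report = report, predictions = predictions, folds = folds)
}
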