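# SEG-CNV: parameter-reduced U-Net for CNV lesion segmentation.
#
# Reference architecture (single-channel input, any size divisible by 16):
#   encoder widths (16, 32, 64, 128), bottleneck 192, four 2x2 max-pool
#   levels; each block is two 3x3 conv + ReLU; decoder blocks are nearest
#   upsample -> concat skip -> two 3x3 conv + ReLU; dropout (p = 0.25) on
#   the two deepest blocks (encoder level 4 and bottleneck); final 1x1 conv
#   + sigmoid. Trainable parameters: 1,556,705 (~1.6 M), independent of the
#   input size because the network is fully convolutional.

SEGCNV_WIDTHS <- c(16L, 32L, 64L, 128L)
SEGCNV_BOTTLENECK <- 192L
SEGCNV_DROPOUT <- 0.25

#' Build the SEG-CNV U-Net
#'
#' @param height,width input size in pixels, each divisible by 16.
#' @param seed seed for weight initialization.
#' @return An object of class \code{segcnvModel}: a list with the layer
#'   parameters, the architecture table (\code{$spec$layers}) and the
#'   trainable parameter count (\code{$spec$trainable_parameter_count}).
#' @export
#' @examples
#' m <- buildSegCNV(128, 128)
#' m$spec$trainable_parameter_count       # 1556705
#' round(m$spec$trainable_parameter_count / 1e6, 1)
buildSegCNV <- function(height = 128L, width = 128L, seed = 1L) {
  if (height %% 16L != 0L || width %% 16L != 0L)
    stop("input height and width must be divisible by 16")
  w <- SEGCNV_WIDTHS; bn <- SEGCNV_BOTTLENECK
  layers <- withSeed(seed, {
    L <- list(
      enc1a = nnConv(1L, w[1]),      enc1b = nnConv(w[1], w[1]),
      enc2a = nnConv(w[1], w[2]),    enc2b = nnConv(w[2], w[2]),
      enc3a = nnConv(w[2], w[3]),    enc3b = nnConv(w[3], w[3]),
      enc4a = nnConv(w[3], w[4]),    enc4b = nnConv(w[4], w[4]),
      bna   = nnConv(w[4], bn),      bnb   = nnConv(bn, bn),
      dec4a = nnConv(bn + w[4], w[4]), dec4b = nnConv(w[4], w[4]),
      dec3a = nnConv(w[4] + w[3], w[3]), dec3b = nnConv(w[3], w[3]),
      dec2a = nnConv(w[3] + w[2], w[2]), dec2b = nnConv(w[2], w[2]),
      dec1a = nnConv(w[2] + w[1], w[1]), dec1b = nnConv(w[1], w[1]),
      out   = nnConv(w[1], 1L, k = 1L, act = "sigmoid"))
    L
  })
  spec <- list(
    input_height = as.integer(height), input_width = as.integer(width),
    input_channels = 1L, encoder_widths = w, bottleneck_width = bn,
    dropout_levels = c("enc4", "bottleneck"), dropout_p = SEGCNV_DROPOUT,
    layers = layerTable(layers),
    trainable_parameter_count = paramCount(layers))
  structure(list(layers = layers, spec = spec), class = "segcnvModel")
}

#' @export
print.segcnvModel <- function(x, ...) {
  cat(sprintf("SEG-CNV U-Net: input %d x %d x 1, widths (%s), bottleneck %d\n",
              x$spec$input_height, x$spec$input_width,
              paste(x$spec$encoder_widths, collapse = ", "),
              x$spec$bottleneck_width))
  cat(sprintf("  trainable parameters: %s (%.1f M)\n",
              format(x$spec$trainable_parameter_count, big.mark = ","),
              x$spec$trainable_parameter_count / 1e6))
  invisible(x)
}

catChannels <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

convPair <- function(la, lb, x) {
  za <- .conv_fw(x, la$W, la$b, la$k); aa <- applyAct(za, la$act)
  zb <- .conv_fw(aa, lb$W, lb$b, lb$k); ab <- applyAct(zb, lb$act)
  list(x = x, za = za, aa = aa, zb = zb, ab = ab)
}

dropoutFw <- function(a, p, training) {
  if (!training || p <= 0) return(list(a = a, mask = NULL))
  mask <- array((runif(length(a)) >= p) / (1 - p), dim(a))
  list(a = a * mask, mask = mask)
}

unetForward <- function(model, img, training = FALSE) {
  L <- model$layers
  x <- asCube(img)
  e1 <- convPair(L$enc1a, L$enc1b, x);  p1 <- .maxpool_fw(e1$ab)
  e2 <- convPair(L$enc2a, L$enc2b, p1$y); p2 <- .maxpool_fw(e2$ab)
  e3 <- convPair(L$enc3a, L$enc3b, p2$y); p3 <- .maxpool_fw(e3$ab)
  e4 <- convPair(L$enc4a, L$enc4b, p3$y)
  d4 <- dropoutFw(e4$ab, SEGCNV_DROPOUT, training)
  p4 <- .maxpool_fw(d4$a)
  bn <- convPair(L$bna, L$bnb, p4$y)
  db <- dropoutFw(bn$ab, SEGCNV_DROPOUT, training)
  u4 <- .upsample_fw(db$a);  c4 <- catChannels(u4, d4$a)
  dd4 <- convPair(L$dec4a, L$dec4b, c4)
  u3 <- .upsample_fw(dd4$ab); c3 <- catChannels(u3, e3$ab)
  dd3 <- convPair(L$dec3a, L$dec3b, c3)
  u2 <- .upsample_fw(dd3$ab); c2 <- catChannels(u2, e2$ab)
  dd2 <- convPair(L$dec2a, L$dec2b, c2)
  u1 <- .upsample_fw(dd2$ab); c1 <- catChannels(u1, e1$ab)
  dd1 <- convPair(L$dec1a, L$dec1b, c1)
  zo <- .conv_fw(dd1$ab, L$out$W, L$out$b, 1L)
  prob <- applyAct(zo, "sigmoid")
  list(prob = prob[, , 1],
       cache = list(e1 = e1, e2 = e2, e3 = e3, e4 = e4, bn = bn,
                    p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                    d4 = d4, db = db,
                    dd4 = dd4, dd3 = dd3, dd2 = dd2, dd1 = dd1,
                    c4 = c4, c3 = c3, c2 = c2, c1 = c1, zo = zo, prob = prob))
}

convPairBw <- function(la, lb, cache, dab, needDx = TRUE) {
  dzb <- actGrad(dab, cache$zb, cache$ab, lb$act)
  gb <- .conv_bw(cache$aa, lb$W, dzb, lb$k, TRUE)
  dza <- actGrad(gb$dx, cache$za, cache$aa, la$act)
  ga <- .conv_bw(cache$x, la$W, dza, la$k, needDx)
  list(ga = list(dW = ga$dW, db = as.numeric(ga$db)),
       gb = list(dW = gb$dW, db = as.numeric(gb$db)),
       dx = ga$dx)
}

splitChannels <- function(d, n1) {
  list(a = d[, , seq_len(n1), drop = FALSE],
       b = d[, , -seq_len(n1), drop = FALSE])
}

unetBackward <- function(model, cache, dProb) {
  L <- model$layers
  g <- list()
  a <- cache$prob
  dzo <- actGrad(asCube(dProb), cache$zo, a, "sigmoid")
  go <- .conv_bw(cache$dd1$ab, L$out$W, dzo, 1L, TRUE)
  g$out <- list(dW = go$dW, db = as.numeric(go$db))
  b1 <- convPairBw(L$dec1a, L$dec1b, cache$dd1, go$dx)
  g$dec1a <- b1$ga; g$dec1b <- b1$gb
  s1 <- splitChannels(b1$dx, dim(cache$dd2$ab)[3])
  dU <- .upsample_bw(s1$a)
  b2 <- convPairBw(L$dec2a, L$dec2b, cache$dd2, dU)
  g$dec2a <- b2$ga; g$dec2b <- b2$gb
  s2 <- splitChannels(b2$dx, dim(cache$dd3$ab)[3])
  dU <- .upsample_bw(s2$a)
  b3 <- convPairBw(L$dec3a, L$dec3b, cache$dd3, dU)
  g$dec3a <- b3$ga; g$dec3b <- b3$gb
  s3 <- splitChannels(b3$dx, dim(cache$dd4$ab)[3])
  dU <- .upsample_bw(s3$a)
  b4 <- convPairBw(L$dec4a, L$dec4b, cache$dd4, dU)
  g$dec4a <- b4$ga; g$dec4b <- b4$gb
  s4 <- splitChannels(b4$dx, dim(cache$db$a)[3])
  dbn <- .upsample_bw(s4$a)
  if (!is.null(cache$db$mask)) dbn <- dbn * cache$db$mask
  bb <- convPairBw(L$bna, L$bnb, cache$bn, dbn)
  g$bna <- bb$ga; g$bnb <- bb$gb
  dE4 <- s4$b + .maxpool_bw(bb$dx, cache$p4$idx)
  if (!is.null(cache$d4$mask)) dE4 <- dE4 * cache$d4$mask
  be4 <- convPairBw(L$enc4a, L$enc4b, cache$e4, dE4)
  g$enc4a <- be4$ga; g$enc4b <- be4$gb
  dE3 <- s3$b + .maxpool_bw(be4$dx, cache$p3$idx)
  be3 <- convPairBw(L$enc3a, L$enc3b, cache$e3, dE3)
  g$enc3a <- be3$ga; g$enc3b <- be3$gb
  dE2 <- s2$b + .maxpool_bw(be3$dx, cache$p2$idx)
  be2 <- convPairBw(L$enc2a, L$enc2b, cache$e2, dE2)
  g$enc2a <- be2$ga; g$enc2b <- be2$gb
  dE1 <- s1$b + .maxpool_bw(be2$dx, cache$p1$idx)
  be1 <- convPairBw(L$enc1a, L$enc1b, cache$e1, dE1, needDx = FALSE)
  g$enc1a <- be1$ga; g$enc1b <- be1$gb
  g[names(model$layers)]
}

# Normalize a training item to list(image, mask) at the model input size.
segTrainItem <- function(item, h, w) {
  if (is(item, "PhantomSample"))
    item <- list(image = outerRetina(item), mask = cnvMask(item))
  list(image = resizeBilinear(item$image, h, w),
       mask = resizeNearest(item$mask, h, w))
}

#' Training configuration for SEG-CNV
#'
#' @param epochs,batch,lr optimizer settings (Adam).
#' @param seed experiment seed covering shuffling, dropout and augmentation.
#' @param augment apply random augmentation (rotation/zoom/flip/shear) to
#'   each training pair.
#' @param augConfig bounds from \code{\link{augmentConfig}}.
#' @return Named list.
#' @export
segTrainConfig <- function(epochs = 50L, batch = 8L, lr = 3e-4, seed = 1L,
                           augment = TRUE, augConfig = augmentConfig()) {
  list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
       seed = as.integer(seed), augment = augment, augConfig = augConfig)
}

#' Train SEG-CNV with soft Dice loss
#'
#' Deterministic given the config seed: weight updates, shuffling, dropout
#' and augmentation all consume one seeded stream. Images are resized to the
#' model input size (bilinear; masks nearest-neighbour).
#'
#' @param model from \code{\link{buildSegCNV}}.
#' @param dataset list of \linkS4class{PhantomSample}s or of
#'   \code{list(image, mask)} pairs.
#' @param config from \code{\link{segTrainConfig}}.
#' @param valDataset optional held-out list evaluated (mean Dice of the
#'   thresholded prediction) after each epoch.
#' @return List with \code{model} (trained) and \code{trace} (data.frame:
#'   epoch, loss, val_dice).
#' @export
trainSegCNV <- function(model, dataset, config = segTrainConfig(),
                        valDataset = NULL) {
  if (length(dataset) == 0) stop("training dataset is empty")
  h <- model$spec$input_height; w <- model$spec$input_width
  items <- lapply(dataset, segTrainItem, h = h, w = w)
  valItems <- if (!is.null(valDataset)) lapply(valDataset, segTrainItem, h = h, w = w)
  layers <- model$layers
  state <- adamInit(lr = config$lr)
  trace <- data.frame(epoch = integer(), loss = numeric(), val_dice = numeric())
  withSeed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(items))
      losses <- numeric()
      for (b0 in seq(1, length(ord), by = config$batch)) {
        ids <- ord[seq(b0, min(b0 + config$batch - 1, length(ord)))]
        acc <- NULL
        for (id in ids) {
          it <- items[[id]]
          img <- it$image; msk <- it$mask
          if (isTRUE(config$augment)) {
            tr <- sampleAugment(config$augConfig)
            img <- applyAugment(img, tr, "bilinear")
            msk <- applyAugment(msk, tr, "nearest")
          }
          fw <- unetForward(model, img, training = TRUE)
          loss <- diceLoss(fw$prob, msk)
          if (!is.finite(loss))
            stop("non-finite Dice loss at epoch ", ep, " (pred range ",
                 paste(range(fw$prob), collapse = ".."), ")")
          losses <- c(losses, loss)
          gr <- unetBackward(model, fw$cache, diceLossGrad(fw$prob, msk))
          acc <- if (is.null(acc)) gr else
            Map(function(a, g) list(dW = a$dW + g$dW, db = a$db + g$db), acc, gr)
        }
        acc <- lapply(acc, function(a)
          list(dW = a$dW / length(ids), db = a$db / length(ids)))
        st <- adamStep(model$layers, acc, state)
        model$layers <- st$layers; state <- st$state
      }
      vd <- NA_real_
      if (!is.null(valItems)) {
        vd <- mean(vapply(valItems, function(it) {
          pr <- unetForward(model, it$image)$prob
          diceCoefficient((pr >= 0.5) * 1, it$mask)
        }, numeric(1)))
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                       val_dice = vd))
    }
  })
  list(model = model, trace = trace)
}

#' Predict a CNV mask
#'
#' The input is resized to the model's input size, passed through the net,
#' thresholded at 0.5 (ties count as foreground) and upsampled back to the
#' original size by nearest neighbour.
#'
#' @param model trained \code{segcnvModel}.
#' @param enface outer-retina grid in \code{[0,1]}.
#' @return 0/1 CNV mask of the same shape as \code{enface}.
#' @export
predictMask <- function(model, enface) {
  assertImage(enface)
  h <- model$spec$input_height; w <- model$spec$input_width
  prob <- unetForward(model, resizeBilinear(enface, h, w))$prob
  resizeNearest(thresholdProb(prob), nrow(enface), ncol(enface))
}

# Documented decision rule: probability >= 0.5 is foreground (ties in).
thresholdProb <- function(prob) (prob >= 0.5) * 1

#' Lesion region of interest
#'
#' Elementwise product of the en-face image and the CNV mask: background is
#' suppressed while the internal vascular structure of the lesion is kept
#' for the downstream classifiers.
#'
#' @param enface grayscale grid.
#' @param mask 0/1 mask of equal shape.
#' @return Matrix \code{enface * mask}.
#' @export
makeROI <- function(enface, mask) {
  assertMask(mask)
  assertSameShape(enface, mask)
  enface * mask
}

#' Small hyperparameter grid search
#'
#' Evaluates a user-supplied scoring function over a learning-rate x batch
#' grid and returns the table with the best cell marked.
#'
#' @param scoreFn function(lr, batch) returning a scalar score (higher is
#'   better, e.g. held-out Dice or accuracy).
#' @param lrs,batches grid values.
#' @return data.frame with columns lr, batch, score, best.
#' @export
gridSearchHyper <- function(scoreFn, lrs = c(1e-3, 1e-4), batches = c(4L, 8L)) {
  grid <- expand.grid(lr = lrs, batch = batches)
  grid$score <- mapply(scoreFn, grid$lr, grid$batch)
  grid$best <- seq_len(nrow(grid)) == which.max(grid$score)
  grid
}
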