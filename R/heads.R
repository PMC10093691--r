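# The five binary activity-criterion classifiers.
#
# Four heads reuse a VGG16 convolutional backbone (transfer learning): the
# backbone is frozen except, per criterion, its last 1 or 3 convolutions,
# and a new fully connected head — global average pool (512) -> dense 419 ->
# dense 1012 -> dense 1 + sigmoid — is trained. That head's trainable total
# is exactly 513*419 + 420*1012 + 1013 = 641,000. The peripheral-arcade
# criterion uses a small network trained from scratch (4 conv blocks + FC +
# sigmoid, all layers trainable).
#
# Pretrained ImageNet backbone weights are optional (loadable from an RDS
# file of conv parameter matrices); by default the backbone is seeded
# random, which preserves the architecture and freeze policy.

VGG_WIDTHS <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
VGG_POOL_AFTER <- c(2, 4, 7, 10, 13)
HEAD_DENSE <- c(419L, 1012L)

#' Classifier configuration table
#'
#' One row per activity criterion: which segmentation output feeds it,
#' whether it is a transfer-learning or from-scratch model, and which layers
#' are trained.
#'
#' @return data.frame with columns feature, input, mode, trained_layers.
#' @export
#' @examples
#' classifierTable()
classifierTable <- function() {
  data.frame(
    feature = c("branch", "shape", "anastomosis_loops", "peripheral_arcade",
                "dark_halo"),
    input = c("CNV ROI", "CNV ROI", "CNV ROI", "Peripheral Arcade Mask",
              "Dark Halo Mask"),
    mode = c("transfer", "transfer", "transfer", "scratch", "transfer"),
    trained_layers = c("FC + Sigmoid", "3Conv + FC + Sigmoid",
                       "1Conv + FC + Sigmoid",
                       "All layers (4Conv + FC + Sigmoid)", "FC + Sigmoid"),
    stringsAsFactors = FALSE)
}

#' Route a segmentation output to its classifier
#'
#' branch, shape and anastomosis_loops consume the CNV ROI; the
#' peripheral-arcade head consumes the peripheral-arcade mask; the dark-halo
#' head consumes the dark-halo mask.
#'
#' @param feature one of \code{octaFeatures()}.
#' @param roi lesion ROI grid.
#' @param paMask,dhMask binary mask grids, same shape as \code{roi}.
#' @return The selected grid, unchanged.
#' @export
routeInput <- function(feature, roi, paMask, dhMask) {
  assertSameShape(roi, paMask); assertSameShape(roi, dhMask)
  switch(feature,
         branch = , shape = , anastomosis_loops = roi,
         peripheral_arcade = paMask,
         dark_halo = dhMask,
         stop("unknown activity criterion: ", feature))
}

#' Preprocess an image for the VGG16 transfer heads
#'
#' Bilinear resize to \code{size x size}, replication to three identical
#' channels, intensities kept in the backbone's expected \code{[0,1]} range.
#'
#' @param image single-channel matrix in \code{[0,1]}.
#' @param size output side (default 224).
#' @return \code{size x size x 3} array.
#' @export
preprocessTransfer <- function(image, size = 224L) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a non-empty matrix")
  g <- resizeBilinear(image, size, size)
  array(rep(g, 3), c(size, size, 3))
}

#' VGG16 layer table and canonical parameter count
#'
#' Closed-form layer listing of the canonical 16-weight-layer VGG
#' (13 convolutions + 3 fully connected layers, 1000-class output, 224 x
#' 224 x 3 input). The parameter total
#' \eqn{\sum (k_h k_w c_{in} c_{out} + c_{out})} over these rows is
#' 138,357,544 (about 138 million).
#'
#' @return data.frame with columns type, kh, kw, cin, cout.
#' @export
#' @examples
#' sum(with(vgg16LayerTable(), kh * kw * cin * cout + cout))   # 138357544
vgg16LayerTable <- function() {
  conv <- data.frame(type = "conv", kh = 3, kw = 3,
                     cin = c(3, head(VGG_WIDTHS, -1)), cout = VGG_WIDTHS)
  fc <- data.frame(type = "dense", kh = 1, kw = 1,
                   cin = c(7 * 7 * 512, 4096, 4096), cout = c(4096, 4096, 1000))
  rbind(conv, fc)
}

vggBackboneLayers <- function(unfreezeLast = 0L) {
  layers <- list()
  trainFrom <- length(VGG_WIDTHS) - unfreezeLast + 1L
  cin <- 3
  for (i in seq_along(VGG_WIDTHS)) {
    layers[[length(layers) + 1]] <- nnConv(cin, VGG_WIDTHS[i],
                                           trainable = i >= trainFrom)
    names(layers)[length(layers)] <- sprintf("conv%d", i)
    cin <- VGG_WIDTHS[i]
    if (i %in% VGG_POOL_AFTER) {
      layers[[length(layers) + 1]] <- nnPool()
      names(layers)[length(layers)] <- sprintf("pool%d", which(VGG_POOL_AFTER == i))
    }
  }
  layers
}

fcHeadLayers <- function() {
  list(gap = nnGAP(),
       fc1 = nnDense(512L, HEAD_DENSE[1]),
       fc2 = nnDense(HEAD_DENSE[1], HEAD_DENSE[2]),
       out = nnDense(HEAD_DENSE[2], 1L, act = "sigmoid"))
}

#' Build a transfer-learning classifier head
#'
#' VGG16 convolutional backbone plus the new fully connected head. The
#' frozen/trained split follows the criterion: \code{branch} and
#' \code{dark_halo} train the FC head only (641,000 parameters);
#' \code{shape} additionally unfreezes the last 3 backbone convolutions;
#' \code{anastomosis_loops} the last 1. The peripheral-arcade criterion is
#' not a transfer model — use \code{\link{buildScratchNet}}.
#'
#' @param feature one of branch, shape, anastomosis_loops, dark_halo.
#' @param inputSize input side in pixels (default 224; any multiple of 32
#'   works because the head pools globally).
#' @param backboneWeights optional RDS file holding a list of 13
#'   \code{list(W, b)} conv parameter sets (e.g. converted ImageNet
#'   weights); when absent the backbone is seeded random.
#' @param seed weight-initialization seed.
#' @return Object of class \code{headModel} with elements \code{layers} and
#'   \code{spec} (a ClassifierSpec list: feature, mode, input_descriptor,
#'   trained_layers, trainable_parameter_count).
#' @export
#' @examples
#' m <- buildTransferHead("dark_halo", inputSize = 32)
#' m$spec$trainable_parameter_count    # 641000
buildTransferHead <- function(feature, inputSize = 224L,
                              backboneWeights = NULL, seed = 1L) {
  if (feature == "peripheral_arcade")
    stop("peripheral_arcade is trained from scratch; use buildScratchNet()")
  tab <- classifierTable()
  if (!feature %in% tab$feature[tab$mode == "transfer"])
    stop("unknown transfer criterion: ", feature)
  if (inputSize %% 32L != 0L) stop("inputSize must be divisible by 32")
  unfreeze <- switch(feature, shape = 3L, anastomosis_loops = 1L, 0L)
  layers <- withSeed(seed, c(vggBackboneLayers(unfreeze), fcHeadLayers()))
  if (!is.null(backboneWeights)) {
    wts <- readRDS(backboneWeights)
    if (!is.list(wts) || length(wts) != length(VGG_WIDTHS))
      stop("malformed backbone weights file: expected 13 conv parameter sets")
    for (i in seq_along(VGG_WIDTHS)) {
      nm <- sprintf("conv%d", i)
      if (!identical(dim(wts[[i]]$W), dim(layers[[nm]]$W)))
        stop("malformed backbone weights file: shape mismatch at ", nm)
      layers[[nm]]$W <- wts[[i]]$W
      layers[[nm]]$b <- as.numeric(wts[[i]]$b)
    }
  }
  spec <- list(feature = feature, mode = "transfer",
               input_descriptor = tab$input[tab$feature == feature],
               trained_layers = tab$trained_layers[tab$feature == feature],
               layers = layerTable(layers),
               trainable_parameter_count = paramCount(layers))
  structure(list(layers = layers, spec = spec,
                 inputSize = as.integer(inputSize)), class = "headModel")
}

#' Build the from-scratch peripheral-arcade network
#'
#' Four 3x3 conv + ReLU + 2x2 max-pool blocks (widths 16, 32, 64, 128), one
#' dense output unit with sigmoid; every parameter is trainable.
#'
#' @param inputSize input side, divisible by 16 (default 128).
#' @param seed weight-initialization seed.
#' @return Object of class \code{headModel}.
#' @export
buildScratchNet <- function(inputSize = 128L, seed = 1L) {
  if (inputSize %% 16L != 0L) stop("inputSize must be divisible by 16")
  w <- c(16L, 32L, 64L, 128L)
  flat <- as.integer((inputSize / 16L)^2 * w[4])
  layers <- withSeed(seed, list(
    conv1 = nnConv(1L, w[1]), pool1 = nnPool(),
    conv2 = nnConv(w[1], w[2]), pool2 = nnPool(),
    conv3 = nnConv(w[2], w[3]), pool3 = nnPool(),
    conv4 = nnConv(w[3], w[4]), pool4 = nnPool(),
    flatten = nnFlatten(),
    out = nnDense(flat, 1L, act = "sigmoid")))
  spec <- list(feature = "peripheral_arcade", mode = "scratch",
               input_descriptor = "Peripheral Arcade Mask",
               trained_layers = "All layers (4Conv + FC + Sigmoid)",
               layers = layerTable(layers),
               trainable_parameter_count = paramCount(layers))
  structure(list(layers = layers, spec = spec,
                 inputSize = as.integer(inputSize)), class = "headModel")
}

#' @export
print.headModel <- function(x, ...) {
  cat(sprintf("%s head (%s): input %d, trained layers: %s, trainable params %s\n",
              x$spec$feature, x$spec$mode, x$inputSize, x$spec$trained_layers,
              format(x$spec$trainable_parameter_count, big.mark = ",")))
  invisible(x)
}

## ---- augmentation ----------------------------------------------------------

#' Augmentation bounds
#'
#' Random rotation, zoom, flips and shear. Bounds are validated: rotation at
#' most +/- 25 degrees, zoom within [0.8, 1.2], shear at most +/- 10 degrees.
#'
#' @param rotation max absolute rotation (degrees).
#' @param zoomMin,zoomMax zoom range.
#' @param hflip,vflip allow horizontal / vertical flips.
#' @param shear max absolute shear (degrees).
#' @return Named list.
#' @export
augmentConfig <- function(rotation = 25, zoomMin = 0.8, zoomMax = 1.2,
                          hflip = TRUE, vflip = TRUE, shear = 10) {
  if (rotation < 0 || rotation > 25) stop("rotation must lie in [0, 25] degrees")
  if (zoomMin < 0.8 || zoomMax > 1.2 || zoomMin > zoomMax)
    stop("zoom range must lie within [0.8, 1.2]")
  if (shear < 0 || shear > 10) stop("shear must lie in [0, 10] degrees")
  list(rotation = rotation, zoomMin = zoomMin, zoomMax = zoomMax,
       hflip = isTRUE(hflip), vflip = isTRUE(vflip), shear = shear)
}

# Draw one transform from the current RNG.
sampleAugment <- function(cfg) {
  list(theta = if (cfg$rotation > 0) runif(1, -cfg$rotation, cfg$rotation) else 0,
       zoom = if (cfg$zoomMax > cfg$zoomMin)
         runif(1, cfg$zoomMin, cfg$zoomMax) else cfg$zoomMin,
       shear = if (cfg$shear > 0) runif(1, -cfg$shear, cfg$shear) else 0,
       hflip = cfg$hflip && runif(1) < 0.5,
       vflip = cfg$vflip && runif(1) < 0.5)
}

augmentMatrix <- function(tr) {
  th <- tr$theta * pi / 180; sh <- tan(tr$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  S <- matrix(c(tr$zoom, 0, 0, tr$zoom), 2)
  Sh <- matrix(c(1, 0, sh, 1), 2)
  Fm <- diag(c(if (tr$hflip) -1 else 1, if (tr$vflip) -1 else 1))
  R %*% Sh %*% S %*% Fm
}

isIdentityTransform <- function(tr) {
  tr$theta == 0 && tr$zoom == 1 && tr$shear == 0 && !tr$hflip && !tr$vflip
}

applyAugment <- function(img, tr, interp = "bilinear") {
  if (isIdentityTransform(tr)) return(img)
  affineWarp(img, augmentMatrix(tr), interp)
}

#' Randomly augment one labelled sample
#'
#' Draws a rotation/zoom/flip/shear transform within the configured bounds
#' from the current RNG and warps the image about its centre (bilinear,
#' out-of-domain pixels 0). The label always passes through unchanged. An
#' identity configuration (rotation 0, zoom fixed at 1, no flips, shear 0)
#' returns the image bit-unchanged.
#'
#' @param image single-channel matrix.
#' @param label 0/1 class label.
#' @param config bounds from \code{\link{augmentConfig}}.
#' @return list(image, label, transform).
#' @export
augmentSample <- function(image, label, config = augmentConfig()) {
  tr <- sampleAugment(config)
  list(image = applyAugment(image, tr), label = label, transform = tr)
}

## ---- training & prediction -------------------------------------------------

#' Training configuration for a classifier head
#'
#' @param epochs,batch epochs and minibatch size.
#' @param lr learning rate; default 1e-4 for transfer heads, 1e-3 for the
#'   scratch net (resolved at \code{\link{trainHead}} time when NULL).
#' @param seed experiment seed (shuffling, augmentation).
#' @param augment apply random augmentation each epoch.
#' @param augConfig bounds from \code{\link{augmentConfig}}.
#' @return Named list.
#' @export
headTrainConfig <- function(epochs = 30L, batch = 8L, lr = NULL, seed = 1L,
                            augment = TRUE, augConfig = augmentConfig()) {
  list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
       seed = as.integer(seed), augment = augment, augConfig = augConfig)
}

headInput <- function(model, image) {
  if (model$spec$mode == "transfer") {
    if (length(dim(image)) == 3) image else
      preprocessTransfer(image, model$inputSize)
  } else {
    asCube(resizeBilinear(if (length(dim(image)) == 3) image[, , 1] else image,
                          model$inputSize, model$inputSize))
  }
}

# Split layers at the lowest trainable one so that the frozen prefix can be
# evaluated once per sample when no augmentation is used.
frozenPrefix <- function(layers) {
  lowest <- Inf
  for (i in seq_along(layers)) if (isTRUE(layers[[i]]$trainable)) { lowest <- i; break }
  if (!is.finite(lowest)) stop("model has no trainable layers")
  lowest
}

#' Train a binary classifier head
#'
#' Binary cross-entropy with Adam; deterministic given the config seed. Both
#' classes must be present. Frozen layers receive no updates (their weights
#' are bit-identical before and after training); when augmentation is off,
#' the frozen prefix is evaluated once per sample and reused across epochs.
#'
#' @param model from \code{\link{buildTransferHead}} or
#'   \code{\link{buildScratchNet}}.
#' @param samples list of \code{list(image, label)} with labels 0/1.
#' @param config from \code{\link{headTrainConfig}}.
#' @return list(model, trace) with a per-epoch loss trace.
#' @export
trainHead <- function(model, samples, config = headTrainConfig()) {
  if (length(samples) == 0) stop("training set is empty")
  y <- vapply(samples, function(s) as.numeric(s$label), numeric(1))
  if (length(unique(y)) < 2)
    stop("training set contains a single class; both classes are required")
  lr <- if (is.null(config$lr)) {
    if (model$spec$mode == "transfer") 1e-4 else 1e-3
  } else config$lr
  split <- frozenPrefix(model$layers)
  prefix <- if (split > 1) model$layers[seq_len(split - 1)] else list()
  suffix <- model$layers[seq(split, length(model$layers))]
  state <- adamInit(lr = lr)
  trace <- data.frame(epoch = integer(), loss = numeric())
  cacheable <- !isTRUE(config$augment) && length(prefix) > 0
  feats <- NULL
  withSeed(config$seed, {
    if (cacheable)
      feats <- lapply(samples, function(s)
        seqForward(prefix, headInput(model, s$image))$out)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(samples))
      losses <- numeric()
      for (b0 in seq(1, length(ord), by = config$batch)) {
        ids <- ord[seq(b0, min(b0 + config$batch - 1, length(ord)))]
        acc <- NULL
        for (id in ids) {
          if (cacheable) {
            x <- feats[[id]]
          } else {
            img <- samples[[id]]$image
            if (isTRUE(config$augment)) {
              g <- if (length(dim(img)) == 3) img[, , 1] else img
              img <- applyAugment(g, sampleAugment(config$augConfig))
            }
            x <- seqForward(prefix, headInput(model, img))$out
          }
          fw <- seqForward(suffix, x)
          p <- fw$out
          losses <- c(losses, bceLoss(p, y[id]))
          gr <- seqBackward(suffix, fw$caches, p - y[id], outIsPreact = TRUE)
          acc <- if (is.null(acc)) gr else
            Map(function(a, g) if (is.null(g)) NULL else
              list(dW = a$dW + g$dW, db = a$db + g$db), acc, gr)
        }
        acc <- lapply(acc, function(a) if (is.null(a)) NULL else
          list(dW = a$dW / length(ids), db = a$db / length(ids)))
        st <- adamStep(suffix, acc, state)
        suffix <- st$layers; state <- st$state
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses)))
    }
  })
  model$layers <- c(prefix, suffix)
  list(model = model, trace = trace)
}

#' Predict one activity criterion
#'
#' @param model a trained \code{headModel}.
#' @param image input grid (routed segmentation output; preprocessing to the
#'   head's input format is applied internally).
#' @return list(feature, probability, label); label is 1 iff probability
#'   >= 0.5.
#' @export
predictFeature <- function(model, image) {
  p <- seqForward(model$layers, headInput(model, image))$out
  list(feature = model$spec$feature, probability = as.numeric(p),
       label = as.integer(p >= 0.5))
}
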