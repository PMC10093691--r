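# Compact CNN engine built on the RcppArmadillo kernels in src/: layer
# constructors, a sequential forward/backward pass, Adam, and the two
# training losses (soft Dice, binary cross-entropy). Weight initialization
# draws from the R RNG, so callers control determinism with one seed.
#
# Tensors are H x W x C arrays (cubes); convolution weights are
# (k*k*Cin) x Cout matrices in the im2col row order of the kernels; dense
# weights are (in x out).

asCube <- function(x) {
  if (length(dim(x)) == 2) array(x, c(dim(x), 1)) else x
}

nnConv <- function(cin, cout, k = 3L, act = c("relu", "sigmoid", "none"),
                   trainable = TRUE) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / (k * k * cin)) else sqrt(1 / (k * k * cin))
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout, act = act,
       trainable = trainable,
       W = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout))
}

nnDense <- function(fin, fout, act = c("relu", "sigmoid", "none"),
                    trainable = TRUE) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / fin) else sqrt(1 / fin)
  list(type = "dense", fin = fin, fout = fout, act = act, trainable = trainable,
       W = matrix(rnorm(fin * fout, sd = sd), fin, fout), b = numeric(fout))
}

nnPool <- function() list(type = "pool", trainable = FALSE)
nnGAP <- function() list(type = "gap", trainable = FALSE)
nnFlatten <- function() list(type = "flatten", trainable = FALSE)

applyAct <- function(z, act) {
  switch(act, relu = pmax(z, 0), sigmoid = 1 / (1 + exp(-z)), none = z)
}

actGrad <- function(da, z, a, act) {
  switch(act,
         relu = da * (z > 0),
         sigmoid = da * a * (1 - a),
         none = da)
}

# Forward through a layer list. Returns list(out, caches). `training` only
# matters for nets with dropout layers (none of the sequential heads here).
seqForward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    cache <- list(x = x)
    if (l$type == "conv") {
      x <- asCube(x)
      cache$x <- x
      z <- .conv_fw(x, l$W, l$b, l$k)
      cache$z <- z
      x <- applyAct(z, l$act)
      cache$a <- x
    } else if (l$type == "pool") {
      p <- .maxpool_fw(asCube(x))
      cache$x <- asCube(cache$x)
      cache$idx <- p$idx
      x <- p$y
    } else if (l$type == "gap") {
      x <- asCube(x)
      cache$x <- x
      cache$dims <- dim(x)
      x <- apply(x, 3, mean)
    } else if (l$type == "flatten") {
      cache$dims <- dim(asCube(x))
      x <- as.numeric(x)
    } else if (l$type == "dense") {
      z <- drop(x %*% l$W) + l$b
      cache$z <- z
      x <- applyAct(z, l$act)
      cache$a <- x
    } else stop("unknown layer type: ", l$type)
    caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

# Backward pass. `dout` is the gradient w.r.t. the network output; when
# `outIsPreact`, it is the gradient w.r.t. the final layer's pre-activation
# (the usual shortcut for sigmoid + cross-entropy). Gradients are only
# produced for trainable layers; dx propagation stops below the lowest one.
seqBackward <- function(layers, caches, dout, outIsPreact = FALSE) {
  grads <- vector("list", length(layers))
  lowest <- Inf
  for (i in seq_along(layers)) {
    if (isTRUE(layers[[i]]$trainable)) { lowest <- i; break }
  }
  d <- dout
  for (i in rev(seq_along(layers))) {
    if (i < lowest) break
    l <- layers[[i]]; cache <- caches[[i]]
    if (l$type == "conv") {
      dz <- if (i == length(layers) && outIsPreact) d
            else actGrad(d, cache$z, cache$a, l$act)
      g <- .conv_bw(cache$x, l$W, asCube(dz), l$k, i > lowest)
      if (l$trainable) grads[[i]] <- list(dW = g$dW, db = as.numeric(g$db))
      d <- g$dx
    } else if (l$type == "pool") {
      d <- .maxpool_bw(asCube(d), cache$idx)
    } else if (l$type == "gap") {
      dims <- cache$dims
      d <- array(rep(d / (dims[1] * dims[2]), each = dims[1] * dims[2]), dims)
    } else if (l$type == "flatten") {
      d <- array(d, cache$dims)
    } else if (l$type == "dense") {
      dz <- if (i == length(layers) && outIsPreact) d
            else actGrad(d, cache$z, cache$a, l$act)
      x <- cache$x
      if (l$trainable)
        grads[[i]] <- list(dW = outer(as.numeric(x), as.numeric(dz)),
                           db = as.numeric(dz))
      if (i > lowest) d <- drop(l$W %*% as.numeric(dz))
    }
  }
  grads
}

paramCount <- function(layers, trainableOnly = TRUE) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W) || (trainableOnly && !isTRUE(l$trainable))) return(0)
    length(l$W) + length(l$b)
  }, numeric(1)))
}

# Layer table (kernel and channel shapes) used by the independent
# closed-form parameter-count oracle.
layerTable <- function(layers) {
  rows <- lapply(layers, function(l) {
    if (l$type == "conv")
      data.frame(type = "conv", kh = l$k, kw = l$k, cin = l$cin, cout = l$cout,
                 trainable = l$trainable)
    else if (l$type == "dense")
      data.frame(type = "dense", kh = 1L, kw = 1L, cin = l$fin, cout = l$fout,
                 trainable = l$trainable)
    else NULL
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

## ---- Adam ------------------------------------------------------------------

adamInit <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = list())
}

# One Adam step over a list of layers given a parallel list of gradients.
adamStep <- function(layers, grads, state) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    key <- as.character(i)
    if (is.null(state$m[[key]]))
      state$m[[key]] <- list(mW = 0 * layers[[i]]$W, vW = 0 * layers[[i]]$W,
                             mb = 0 * layers[[i]]$b, vb = 0 * layers[[i]]$b)
    s <- state$m[[key]]
    s$mW <- state$beta1 * s$mW + (1 - state$beta1) * grads[[i]]$dW
    s$vW <- state$beta2 * s$vW + (1 - state$beta2) * grads[[i]]$dW^2
    s$mb <- state$beta1 * s$mb + (1 - state$beta1) * grads[[i]]$db
    s$vb <- state$beta2 * s$vb + (1 - state$beta2) * grads[[i]]$db^2
    layers[[i]]$W <- layers[[i]]$W - state$lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + state$eps)
    layers[[i]]$b <- layers[[i]]$b - state$lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + state$eps)
    state$m[[key]] <- s
  }
  list(layers = layers, state = state)
}

## ---- losses ----------------------------------------------------------------

#' Soft Dice loss
#'
#' \code{1 - (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)} for a
#' probability grid against a binary ground-truth mask. Equals
#' \code{1 - diceCoefficient(pred, gt)} for binary predictions (up to the
#' smoothing term), and is symmetric in its arguments.
#'
#' @param pred numeric matrix in \code{[0,1]}.
#' @param gt 0/1 matrix of equal shape.
#' @param eps smoothing added to numerator and denominator to avoid 0/0 on
#'   empty masks.
#' @return Scalar loss in \code{[0,1]}.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' diceLoss(m, m)            # ~0
#' diceLoss(m, 1 - m)        # ~1
diceLoss <- function(pred, gt, eps = 1e-6) {
  assertSameShape(pred, gt)
  if (min(pred) < 0 || max(pred) > 1) stop("pred must lie in [0, 1]")
  1 - (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)
}

# Gradient of the soft Dice loss w.r.t. the prediction grid.
diceLossGrad <- function(pred, gt, eps = 1e-6) {
  A <- sum(pred); B <- sum(gt); I <- sum(pred * gt)
  den <- A + B + eps
  -(2 * gt * den - (2 * I + eps)) / den^2
}

bceLoss <- function(p, y, eps = 1e-12) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
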