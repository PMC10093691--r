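# Shared internal helpers: validation, seeding, rounding, resizing, warping.

clip01 <- function(x) pmin(pmax(x, 0), 1)  # matrix-first: pmin/pmax keep dims of arg 1

isBinaryMask <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

assertMask <- function(m, what = "mask") {
  if (!isBinaryMask(m)) stop(what, " must be a numeric matrix with values in {0, 1}")
  invisible(m)
}

assertSameShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " must have identical dimensions (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
  }
  invisible(NULL)
}

assertImage <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop(what, " intensities must lie in [0, 1] with no missing values")
  }
  invisible(x)
}

# Run expr under a given RNG seed, restoring the caller's RNG state on exit.
# All package randomness flows through this helper so that a single seed
# reproduces any result bit-for-bit without disturbing the session RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Independent sub-seeds derived from one master seed. Always draws the full
# vector so that component k's seed does not depend on how many components
# are actually used (feature-toggle locality relies on this).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() uses round-half-even).
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Bilinear resize of a [0,1] matrix via EBImage (which stores images
# transposed, width x height).
resizeBilinear <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  out <- EBImage::resize(EBImage::Image(t(img)), w = w, h = h, filter = "bilinear")
  clip01(t(EBImage::imageData(out)))
}

# Nearest-neighbour resize; exact for binary masks.
resizeNearest <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  ri <- floor((seq_len(h) - 0.5) / h * nrow(img)) + 1L
  ci <- floor((seq_len(w) - 0.5) / w * ncol(img)) + 1L
  img[ri, ci, drop = FALSE]
}

# Inverse-mapped affine warp about the image centre with bilinear (or
# nearest) sampling; out-of-domain samples are 0. `mat` is the 2x2 forward
# transform acting on (x, y) offsets, x rightwards, y downwards.
affineWarp <- function(img, mat, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  inv <- solve(mat)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  gx <- rep(seq_len(W) - 1 - cx, each = H)
  gy <- rep(seq_len(H) - 1 - cy, times = W)
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + cx
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + cy
  if (interp == "nearest") {
    r <- round(sy) + 1; c <- round(sx) + 1
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out <- numeric(H * W)
    out[ok] <- img[cbind(r[ok], c[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    out <- numeric(H * W)
    pick <- function(r, c) {
      ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
      v <- numeric(length(r)); v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
      v
    }
    out <- (1 - fr) * (1 - fc) * pick(r0, c0) +
           fr       * (1 - fc) * pick(r0 + 1, c0) +
           (1 - fr) * fc       * pick(r0, c0 + 1) +
           fr       * fc       * pick(r0 + 1, c0 + 1)
  }
  matrix(out, H, W)
}
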