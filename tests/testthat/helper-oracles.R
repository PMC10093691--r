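# Independent brute-force oracles used across the suite. These are written
# directly from the definitions (per-pixel loops, BFS flood fill, set
# algebra, closed-form layer sums) and never call the package code paths
# they check.

# Binary dilation: output pixel is 1 iff any kernel-covered input pixel is 1.
bfDilate <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask); p <- (nrow(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 0
    for (di in -p:p) for (dj in -p:p) {
      if (kern[di + p + 1, dj + p + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] == 1) v <- 1
    }
    out[i, j] <- v
  }
  out
}

# Binary erosion: 1 iff every kernel-covered in-bounds position is 1 and no
# kernel element falls outside the image (matches EBImage border handling
# for masks that do not touch the border; fixtures keep a margin).
bfErode <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask); p <- (nrow(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 1
    for (di in -p:p) for (dj in -p:p) {
      if (kern[di + p + 1, dj + p + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || mask[ii, jj] == 0) v <- 0
    }
    out[i, j] <- v
  }
  out
}

# Truncated-window local statistics by direct per-pixel summation.
bfLocalStats <- function(img, win) {
  H <- nrow(img); W <- ncol(img); p <- (win - 1) / 2
  mu <- mn <- mx <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rs <- max(1, i - p):min(H, i + p)
    cs <- max(1, j - p):min(W, j + p)
    v <- img[rs, cs]
    mu[i, j] <- mean(v); mn[i, j] <- min(v); mx[i, j] <- max(v)
  }
  list(mean = mu, min = mn, max = mx)
}

# Breadth-first flood fill with the fixed seed-mean criterion.
bfFloodFill <- function(img, seeds, tol) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W); seen <- matrix(FALSE, H, W)
  m <- mean(img[seeds + 1L])
  queue <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  for (s in queue) { seen[s[1] + 1, s[2] + 1] <- TRUE; out[s[1] + 1, s[2] + 1] <- 1 }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))) {
      q <- p + d
      if (q[1] < 0 || q[1] >= H || q[2] < 0 || q[2] >= W) next
      if (seen[q[1] + 1, q[2] + 1]) next
      seen[q[1] + 1, q[2] + 1] <- TRUE
      if (abs(img[q[1] + 1, q[2] + 1] - m) <= tol) {
        out[q[1] + 1, q[2] + 1] <- 1
        queue <- c(queue, list(q))
      }
    }
  }
  out
}

# Closed-form parameter count: sum of kh*kw*cin*cout + cout over layer rows.
bfLayerParamSum <- function(layerTable, trainableOnly = TRUE) {
  t <- layerTable
  if (trainableOnly && "trainable" %in% names(t)) t <- t[t$trainable, ]
  as.numeric(sum(t$kh * t$kw * t$cin * t$cout + t$cout))
}

# Exhaustive confusion tabulation.
bfConfusion <- function(preds, labels) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(preds)) {
    if (preds[i] == 1 && labels[i] == 1) tp <- tp + 1
    if (preds[i] == 1 && labels[i] == 0) fp <- fp + 1
    if (preds[i] == 0 && labels[i] == 0) tn <- tn + 1
    if (preds[i] == 0 && labels[i] == 1) fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Random binary mask fixture with a clear margin.
randomMask <- function(n, p = 0.3, margin = 0) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  if (margin > 0) {
    m[seq_len(margin), ] <- 0; m[n - seq_len(margin) + 1, ] <- 0
    m[, seq_len(margin)] <- 0; m[, n - seq_len(margin) + 1] <- 0
  }
  m
}

# Small phantom settings shared by several tests.
testPhantomConfig <- function(seed = 1L, toggles = setNames(rep(TRUE, 5), octaFeatures()),
                              imageSize = 128L) {
  phantomConfig(imageSize = imageSize, lesionRadius = round(imageSize * 0.2),
                haloWidth = max(4, round(imageSize * 0.05)),
                featureToggles = toggles, seed = seed)
}
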