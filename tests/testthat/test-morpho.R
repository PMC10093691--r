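test_that("ring mask of a single pixel with outward 1 is its 8-neighbourhood", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  ring <- ringMask(m, 1, 0)
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1; expected[3, 3] <- 0
  expect_identical(ring, expected)
})

test_that("ring mask handles empty and full masks", {
  expect_identical(ringMask(matrix(0, 6, 6) + 0, 2), matrix(0, 6, 6))
  full <- matrix(1, 6, 6)
  expect_identical(ringMask(full, 2, 0), matrix(0, 6, 6))
  expect_error(ringMask(matrix(0, 4, 4), 0), ">= 1")
})

test_that("dilation and erosion match exhaustive set-algebra oracles", {
  set.seed(11)
  for (n in c(16, 33, 64)) {
    for (r in c(1L, 2L, 3L)) {
      m <- randomMask(n, 0.25, margin = r + 1)
      k <- diskElement(r)
      expect_identical(dilateMask(m, r), bfDilate(m, k),
                       info = sprintf("dilate n=%d r=%d", n, r))
      expect_identical(erodeMask(m, r), bfErode(m, k),
                       info = sprintf("erode n=%d r=%d", n, r))
    }
  }
})

test_that("ring area is monotone in both radii", {
  set.seed(12)
  m <- matrix(0, 32, 32); m[10:20, 12:22] <- 1
  areas_o <- sapply(1:5, function(o) sum(ringMask(m, o, 2)))
  areas_i <- sapply(0:5, function(i) sum(ringMask(m, 3, i)))
  expect_true(all(diff(areas_o) >= 0))
  expect_true(all(diff(areas_i) >= 0))
})

test_that("vessel binarization matches the per-pixel local-statistics oracle", {
  set.seed(13)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(1, 32, 32)
  for (win in c(3L, 15L)) {
    for (off in c(0, 0.05)) {
      st <- bfLocalStats(img, win)
      expected <- (img > st$mean - off * (st$max - st$min)) * 1
      expect_identical(binarizeVessels(img, mask, win, off), expected,
                       info = sprintf("win=%d off=%g", win, off))
    }
  }
})

test_that("binarization tie rule: a constant image yields no vessels", {
  img <- matrix(0.4, 16, 16)
  expect_identical(binarizeVessels(img, matrix(1, 16, 16), 15, 0),
                   matrix(0, 16, 16))
  expect_error(binarizeVessels(img, matrix(1, 16, 16), 4), "odd")
})

test_that("a bright one-pixel line binarizes to exactly the line inside the mask", {
  img <- matrix(0, 31, 31); img[16, ] <- 1
  mask <- matrix(0, 31, 31); mask[10:22, 8:24] <- 1
  out <- binarizeVessels(img, mask, 15, 0)
  expected <- matrix(0, 31, 31); expected[16, 8:24] <- 1
  expect_identical(out, expected)
})

test_that("inverting intensities swaps the within-window contrast classes", {
  set.seed(14)
  img <- matrix(runif(256), 16, 16)
  mask <- matrix(1, 16, 16)
  a <- binarizeVessels(img, mask, 5, 0)
  b <- binarizeVessels(1 - img, mask, 5, 0)
  # oracle: strict exceedance of the local mean flips to strict deficit
  st <- bfLocalStats(img, 5)
  expect_identical(a, (img > st$mean) * 1)
  expect_identical(b, (img < st$mean) * 1)
  expect_true(all(a * b == 0))
})

test_that("in-mask inversion matches its truth table exhaustively", {
  set.seed(15)
  b <- randomMask(8, 0.5); m <- randomMask(8, 0.5)
  out <- invertWithinMask(b, m)
  for (i in 1:8) for (j in 1:8)
    expect_identical(out[i, j], if (m[i, j] == 1) 1 - b[i, j] else 0)
  expect_identical(invertWithinMask(m, m), matrix(0, 8, 8))
  expect_identical(invertWithinMask(matrix(0, 8, 8), m), m * 1)
})

test_that("region growing floods a uniform image entirely", {
  img <- matrix(0.5, 12, 12)
  out <- regionGrow(img, cbind(5L, 5L), tolerance = 0.1)
  expect_identical(out, matrix(1, 12, 12))
})

test_that("region growing recovers a dark annulus exactly", {
  n <- 64
  img <- matrix(0.8, n, n)
  rr <- matrix(seq_len(n) - 1, n, n); cc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  dist2 <- (rr - 31.5)^2 + (cc - 31.5)^2
  img[dist2 <= 20^2] <- 0.2          # annulus value (filled below by disk)
  img[dist2 <= 12^2] <- 0.9          # bright disk inside
  annulus <- (dist2 <= 20^2 & dist2 > 12^2) * 1
  seed <- which(annulus == 1, arr.ind = TRUE)[1, , drop = FALSE] - 1L
  out <- regionGrow(img, seed, tolerance = 0.3)
  expect_identical(out, annulus)
  expect_identical(bfFloodFill(img, seed, 0.3), annulus)
})

test_that("tolerance zero grows exactly the equal-intensity connected component", {
  set.seed(16)
  img <- matrix(sample(c(0.1, 0.4, 0.7), 400, replace = TRUE), 20, 20)
  img[5:9, 5:9] <- 0.95
  out <- regionGrow(img, cbind(6L, 6L), tolerance = 0)
  expect_identical(out, bfFloodFill(img, cbind(6L, 6L), 0))
  expect_true(all(out[5:9, 5:9] == 1))
  expect_identical(sum(out), 25)
})

test_that("fixed-mean region growing equals the BFS flood-fill oracle on random grids", {
  set.seed(17)
  for (rep in 1:5) {
    img <- matrix(runif(24 * 24), 24, 24)
    seeds <- cbind(sample(0:23, 2), sample(0:23, 2))
    tol <- runif(1, 0.05, 0.4)
    expect_identical(regionGrow(img, seeds, tol, criterion = "fixed"),
                     bfFloodFill(img, seeds, tol))
  }
})

test_that("region growing always contains its seeds and is 4-connected-closed", {
  set.seed(18)
  img <- matrix(runif(100), 10, 10)
  seeds <- cbind(c(2L, 7L), c(3L, 8L))
  out <- regionGrow(img, seeds, 0.2)
  expect_true(all(out[seeds + 1L] == 1))
  expect_error(regionGrow(img, seeds[0, , drop = FALSE], 0.2), "non-empty")
  expect_error(regionGrow(img, seeds, -1), ">= 0")
})

test_that("contrast enhancement preserves range and leaves constants alone", {
  c0 <- matrix(0.3, 64, 64)
  expect_identical(enhanceChoroid(c0), c0)
  set.seed(19)
  img <- pmin(pmax(matrix(0.5 + 0.05 * rnorm(64 * 64), 64, 64), 0), 1)
  out <- enhanceChoroid(img)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  entropy <- function(x) {
    p <- tabulate(findInterval(x, seq(0, 1, length.out = 65)), 65) / length(x)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  expect_gte(entropy(out), entropy(img))
})

test_that("SEG-PA equals its three primitives composed, and respects vessels", {
  set.seed(20)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(0, 32, 32); mask[12:22, 12:22] <- 1
  params <- morphoParams(window = 7, offset = 0.05, ringOutward = 3, ringInward = 3)
  out <- segPA(img, mask, params)
  ro <- max(1L, as.integer(round(3 * 32 / 304)))
  region <- dilateMask(mask, ro)
  vessels <- binarizeVessels(img, region, 7, 0.05)
  expected <- ringMask(mask, ro, ro) * invertWithinMask(vessels, region)
  expect_identical(out, expected)
  expect_true(all(out * vessels == 0))
  # binarization covering the whole region leaves an empty arcade mask
  expect_identical(ringMask(mask, ro, ro) * invertWithinMask(region, region),
                   matrix(0, 32, 32))
})

test_that("removing the marginal arcade opens up more inter-vessel space", {
  on <- generatePhantomPair(testPhantomConfig(seed = 23L))
  tg <- setNames(rep(TRUE, 5), octaFeatures()); tg["peripheral_arcade"] <- FALSE
  off <- generatePhantomPair(testPhantomConfig(seed = 23L, toggles = tg))
  paOn <- segPA(outerRetina(on), cnvMask(on))
  paOff <- segPA(outerRetina(off), cnvMask(off))
  expect_gt(sum(paOn), 0)
  expect_gt(sum(paOff), sum(paOn))
})

test_that("SEG-DH output is disjoint from the lesion and bounded by the search ring", {
  s <- generatePhantomPair(testPhantomConfig(seed = 24L))
  dh <- segDH(choriocapillaris(s), cnvMask(s))
  expect_equal(sum(dh * cnvMask(s)), 0)
  search <- ringMask(cnvMask(s), max(1L, as.integer(round(30 * 128 / 304))), 0)
  expect_true(all(dh <= search))
  expect_error(segDH(choriocapillaris(s), matrix(0, 128, 128)), "empty")
})

test_that("a uniformly bright choriocapillaris yields no halo", {
  pad <- matrix(0, 40, 40); pad[11:27, 11:27] <- diskElement(8)
  bright <- matrix(0.9, 40, 40)
  dh <- segDH(bright, pad, morphoParams(tolerance = 0.01))
  expect_identical(dh, matrix(0, 40, 40))
})
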