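test_that("regeneration with the same config and seed is bit-identical", {
  cfg <- testPhantomConfig(seed = 42L)
  a <- generatePhantomPair(cfg)
  b <- generatePhantomPair(cfg)
  expect_identical(outerRetina(a), outerRetina(b))
  expect_identical(choriocapillaris(a), choriocapillaris(b))
  expect_identical(cnvMask(a), cnvMask(b))
  expect_identical(paMask(a), paMask(b))
  expect_identical(dhMask(a), dhMask(b))
  expect_identical(activityLabels(a), activityLabels(b))
})

test_that("dark halo darkens the choriocapillaris annulus relative to just outside", {
  s <- generatePhantomPair(testPhantomConfig(seed = 7L))
  ch <- choriocapillaris(s)
  inside <- dhMask(s)
  w <- max(4, round(128 * 0.05))
  beyond <- ringMask(dilateMask(cnvMask(s), w), w, 0)  # equal-width annulus outside
  expect_gt(sum(inside), 0)
  expect_lt(mean(ch[inside == 1]), mean(ch[beyond == 1]))
})

test_that("with all features off and no noise the lesion is exactly the spoke skeleton", {
  cfg <- phantomConfig(imageSize = 128L, lesionRadius = 25, haloWidth = 5,
                       vesselWidth = 1, nSpokes = 8L, noiseSigma = 0,
                       featureToggles = setNames(rep(FALSE, 5), octaFeatures()),
                       seed = 3L)
  s <- generatePhantomPair(cfg)
  # analytically drawn spokes: straight Bresenham lines centre -> tip
  ctr <- c(63.5, 63.5); r <- 25
  ang <- 2 * pi * (0:7) / 8
  px <- do.call(rbind, lapply(ang, function(a)
    bresenhamLine(ctr[1], ctr[2], ctr[1] + r * sin(a), ctr[2] + r * cos(a))))
  px <- px[!duplicated(px), ]
  fg <- which(outerRetina(s) > 0.5, arr.ind = TRUE) - 1L
  expect_equal(nrow(fg), nrow(px))
  expect_setequal(paste(fg[, 1], fg[, 2]), paste(px[, 1], px[, 2]))
})

test_that("each toggle changes the render only inside its support region", {
  base <- setNames(rep(FALSE, 5), octaFeatures())
  offS <- generatePhantomPair(testPhantomConfig(seed = 9L, toggles = base))
  for (f in octaFeatures()) {
    tg <- base; tg[f] <- TRUE
    s <- generatePhantomPair(testPhantomConfig(seed = 9L, toggles = tg))
    dOuter <- abs(outerRetina(s) - outerRetina(offS)) > 1e-12
    dChor <- abs(choriocapillaris(s) - choriocapillaris(offS)) > 1e-12
    expect_true(any(dOuter) || any(dChor), info = f)   # toggle provably changes the image
    if (f == "dark_halo") {
      expect_false(any(dOuter), info = f)
      expect_true(all(dChor[dhMask(s) == 0] == FALSE), info = f)
    } else {
      expect_false(any(dChor), info = f)
      # every changed pixel lies within a vessel-width of the toggled
      # render's own lesion mask (dilation can poke past the outline)
      supp <- dilateMask(cnvMask(s), 2L)
      expect_true(all(which(dOuter) %in% which(supp == 1)), info = f)
    }
  }
})

test_that("ground-truth masks satisfy their containment invariants", {
  s <- generatePhantomPair(testPhantomConfig(seed = 5L))
  ringR <- max(2L, round(5 * 128 / 304))
  ring <- ringMask(cnvMask(s), ringR, ringR)
  expect_true(all(paMask(s) <= ring))
  halo <- dilateMask(cnvMask(s), round(max(4, round(128 * 0.05)))) * (1 - cnvMask(s))
  expect_true(all(dhMask(s) <= halo))
  expect_equal(sum(dhMask(s) * cnvMask(s)), 0)
})

test_that("degenerate prevalences give all-ones / all-zeros labels", {
  base <- testPhantomConfig(imageSize = 64L)
  d1 <- generatePhantomDataset(3, 2, prevalence = rep(1, 5), baseConfig = base,
                               seed = 2L, keepSamples = FALSE)
  expect_true(all(as.matrix(d1$samples[, octaFeatures()]) == 1))
  d0 <- generatePhantomDataset(3, 2, prevalence = rep(0, 5), baseConfig = base,
                               seed = 2L, keepSamples = FALSE)
  expect_true(all(as.matrix(d0$samples[, octaFeatures()]) == 0))
  expect_error(generatePhantomDataset(3, 2, prevalence = rep(1.5, 5),
                                      baseConfig = base), "prevalence")
  expect_error(generatePhantomDataset(0, 2, baseConfig = base), ">= 1")
})

test_that("observed prevalence stays within 3 binomial SDs at n = 100", {
  d <- generatePhantomDataset(50, 2, prevalence = rep(0.5, 5),
                              baseConfig = testPhantomConfig(imageSize = 64L),
                              seed = 31L, keepSamples = FALSE)
  p <- colMeans(as.matrix(d$samples[, octaFeatures()]))
  expect_true(all(abs(p - 0.5) <= 3 * sqrt(0.25 / 100)))
  # subject grouping: images_per_subject images per subject id
  expect_true(all(table(d$samples$subject_id) == 2))
})

test_that("invalid lesion geometry is rejected", {
  expect_error(phantomConfig(imageSize = 64L, lesionRadius = 40),
               "exceeds image bounds")
  expect_error(phantomConfig(lesionRadius = -2), "positive")
  expect_error(phantomConfig(haloContrast = 1.2), "haloContrast")
})

test_that("a written dataset round-trips through its manifest", {
  dir <- withr::local_tempdir()
  base <- testPhantomConfig(imageSize = 64L)
  d <- generatePhantomDataset(3, 2, prevalence = rep(0.5, 5), baseConfig = base,
                              seed = 8L, dir = dir, keepSamples = TRUE)
  man <- readManifest(file.path(dir, "manifest.json"))
  expect_equal(nrow(man$samples), 6)
  loaded <- loadManifestSamples(man)
  for (i in seq_along(loaded)) {
    expect_identical(cnvMask(loaded[[i]]), cnvMask(d$phantoms[[i]]))
    expect_identical(activityLabels(loaded[[i]]), activityLabels(d$phantoms[[i]]))
    expect_lte(max(abs(outerRetina(loaded[[i]]) - outerRetina(d$phantoms[[i]]))),
               1 / 255)
  }
  labs <- readLabels(file.path(dir, "labels.csv"))
  expect_equal(labs$subject_id, d$samples$subject_id)
  expect_equal(labs$dark_halo, d$samples$dark_halo)
})
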