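test_that("the five heads reproduce the classifier configuration row-for-row", {
  tab <- classifierTable()
  expect_identical(tab$feature, octaFeatures())
  expect_identical(tab$mode == "scratch", tab$feature == "peripheral_arcade")
  expect_identical(tab$input[tab$feature %in%
                     c("branch", "shape", "anastomosis_loops")],
                   rep("CNV ROI", 3))
  # built models agree with the table
  for (f in c("branch", "shape", "anastomosis_loops", "dark_halo")) {
    m <- buildTransferHead(f, inputSize = 32)
    expect_identical(m$spec$trained_layers,
                     tab$trained_layers[tab$feature == f])
    expect_identical(m$spec$input_descriptor, tab$input[tab$feature == f])
  }
  sc <- buildScratchNet(32)
  expect_identical(sc$spec$trained_layers, "All layers (4Conv + FC + Sigmoid)")
  expect_true(all(vapply(sc$layers, function(l)
    is.null(l$W) || isTRUE(l$trainable), logical(1))))
})

test_that("segmentation outputs are routed to the right heads", {
  roi <- matrix(0.5, 4, 4); pa <- matrix(1, 4, 4); dh <- matrix(0, 4, 4)
  expect_identical(routeInput("branch", roi, pa, dh), roi)
  expect_identical(routeInput("shape", roi, pa, dh), roi)
  expect_identical(routeInput("anastomosis_loops", roi, pa, dh), roi)
  expect_identical(routeInput("peripheral_arcade", roi, pa, dh), pa)
  expect_identical(routeInput("dark_halo", roi, pa, dh), dh)
  expect_error(routeInput("unknown", roi, pa, dh), "unknown activity criterion")
})

test_that("transfer preprocessing resizes and replicates channels", {
  const <- matrix(0.5, 224, 224)
  out <- preprocessTransfer(const)
  expect_identical(dim(out), c(224L, 224L, 3L))
  expect_true(all(abs(out - 0.5) < 1e-12))
  expect_identical(out[, , 1], out[, , 3])
  checker <- matrix(rep(c(0, 1), length.out = 448 * 448), 448, 448)
  expect_identical(dim(preprocessTransfer(checker)), c(224L, 224L, 3L))
  same <- matrix(runif(224 * 224), 224, 224)
  expect_identical(preprocessTransfer(same)[, , 2], same)
  expect_error(preprocessTransfer(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("FC-only transfer heads train exactly the recorded 641,000 parameters", {
  for (f in c("dark_halo", "branch")) {
    m <- buildTransferHead(f, inputSize = 32)
    oracle <- bfLayerParamSum(m$spec$layers, trainableOnly = TRUE)
    expect_identical(m$spec$trainable_parameter_count, oracle)
    expect_identical(oracle, 513 * 419 + 420 * 1012 + 1013)
    expect_identical(oracle, 641000)
  }
})

test_that("partially unfrozen heads free exactly the last 1 or 3 backbone convolutions", {
  m3 <- buildTransferHead("shape", inputSize = 32)
  convs <- grep("^conv", names(m3$layers), value = TRUE)
  trainableConvs <- convs[vapply(m3$layers[convs], `[[`, logical(1), "trainable")]
  expect_identical(trainableConvs, c("conv11", "conv12", "conv13"))
  m1 <- buildTransferHead("anastomosis_loops", inputSize = 32)
  trainable1 <- convs[vapply(m1$layers[convs], `[[`, logical(1), "trainable")]
  expect_identical(trainable1, "conv13")
  expect_error(buildTransferHead("peripheral_arcade"), "buildScratchNet")
})

test_that("the full VGG16 reference sums to 138 million parameters", {
  total <- bfLayerParamSum(vgg16LayerTable(), trainableOnly = FALSE)
  expect_identical(total, 138357544)
  expect_identical(round(total / 1e6), 138)
})

test_that("builds are seed-reproducible and the scratch count matches its oracle", {
  a <- buildScratchNet(64, seed = 5); b <- buildScratchNet(64, seed = 5)
  expect_identical(a$layers, b$layers)
  expect_identical(a$spec$trainable_parameter_count,
                   bfLayerParamSum(a$spec$layers))
  ta <- buildTransferHead("dark_halo", inputSize = 32, seed = 5)
  tb <- buildTransferHead("dark_halo", inputSize = 32, seed = 5)
  expect_identical(ta$layers, tb$layers)
})

test_that("augmentation bounds are enforced and flips are involutions", {
  expect_error(augmentConfig(rotation = 30), "rotation")
  expect_error(augmentConfig(zoomMin = 0.5), "zoom")
  expect_error(augmentConfig(shear = 15), "shear")
  set.seed(7)
  img <- matrix(runif(64 * 64), 64, 64)
  tr <- list(theta = 0, zoom = 1, shear = 0, hflip = TRUE, vflip = FALSE)
  once <- octacnv:::applyAugment(img, tr)
  twice <- octacnv:::applyAugment(once, tr)
  expect_false(identical(once, img))
  expect_equal(twice, img, tolerance = 1e-12)
  # label passes through
  out <- augmentSample(img, 0L)
  expect_identical(out$label, 0L)
})

test_that("frozen layers stay bit-identical through a training step", {
  set.seed(8)
  m <- buildTransferHead("anastomosis_loops", inputSize = 32, seed = 2)
  before <- m$layers
  samples <- list(list(image = matrix(runif(1024), 32, 32), label = 1L),
                  list(image = matrix(runif(1024), 32, 32), label = 0L))
  fit <- trainHead(m, samples, headTrainConfig(epochs = 1, batch = 2, seed = 2,
                                               augment = FALSE))
  after <- fit$model$layers
  for (i in 1:10)
    expect_identical(after[[sprintf("conv%d", i)]]$W,
                     before[[sprintf("conv%d", i)]]$W, info = i)
  expect_false(identical(after$conv13$W, before$conv13$W))
  expect_false(identical(after$out$W, before$out$W))
})

test_that("a two-sample set is memorized and single-class sets are rejected", {
  set.seed(9)
  s1 <- list(image = matrix(runif(1024), 32, 32), label = 1L)
  s0 <- list(image = matrix(runif(1024) * 0.2, 32, 32), label = 0L)
  m <- buildScratchNet(32, seed = 3)
  fit <- trainHead(m, list(s1, s0),
                   headTrainConfig(epochs = 40, batch = 2, seed = 3,
                                   augment = FALSE))
  expect_lt(tail(fit$trace$loss, 1), fit$trace$loss[1])
  expect_identical(predictFeature(fit$model, s1$image)$label, 1L)
  expect_identical(predictFeature(fit$model, s0$image)$label, 0L)
  expect_error(trainHead(m, list(s1, s1), headTrainConfig()), "single class")
  expect_error(trainHead(m, list(), headTrainConfig()), "empty")
})

test_that("prediction labels follow the >= 0.5 tie rule", {
  m <- buildScratchNet(32, seed = 1)
  # zero the output layer: sigmoid(0) = 0.5 exactly -> label 1
  m$layers$out$W[] <- 0; m$layers$out$b[] <- 0
  p <- predictFeature(m, matrix(runif(1024), 32, 32))
  expect_identical(p$probability, 0.5)
  expect_identical(p$label, 1L)
  m$layers$out$b[] <- -0.1
  expect_identical(predictFeature(m, matrix(runif(1024), 32, 32))$label, 0L)
})
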