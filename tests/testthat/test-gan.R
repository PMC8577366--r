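test_that("network configs enforce the architectural invariants", {
  cfg <- ganGeneratorConfig()
  expect_equal(cfg$inputSide, 2L * cfg$outputSide)
  expect_equal(cfg$nDown, cfg$nUp + 1L)
  expect_error(ganGeneratorConfig(inputSide = 64, outputSide = 16),
               "inputSide")
  expect_error(ganGeneratorConfig(nDown = 4, nUp = 4), "nDown")
  expect_error(ganGeneratorConfig(leakyAlpha = 1.5), "leakyAlpha")
  expect_error(ganTrainConfig(epochs = 0), "invalid")
  tc <- ganTrainConfig()
  expect_equal(unname(tc$lossWeights), c(1, 100))
  expect_equal(tc$lr, 2e-4)
  expect_equal(tc$beta1, 0.5)
  expect_equal(tc$batchSize, 16L)
})

test_that("convolution kernels match numerical gradients", {
  withr::local_seed(10)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  numGrad <- function(f, a, eps = 1e-6) {
    g <- array(0, dim(a))
    for (i in seq_along(a)) {
      a1 <- a; a1[i] <- a[i] + eps
      a2 <- a; a2[i] <- a[i] - eps
      g[i] <- (f(a1) - f(a2)) / (2 * eps)
    }
    g
  }
  for (op in c("conv", "convt")) {
    p <- nanoelast:::convLayerInit(4, 4, 2, 3)
    fw <- if (op == "conv") nanoelast:::convFw else nanoelast:::convtFw
    bw <- if (op == "conv") nanoelast:::convBw else nanoelast:::convtBw
    y <- fw(p, x, 2L, 1L)
    gy <- array(rnorm(length(y)), dim(y))
    gr <- bw(p, x, gy, 2L, 1L)
    gXnum <- numGrad(function(a) sum(fw(p, a, 2L, 1L) * gy), x)
    expect_lt(max(abs(gXnum - gr$gx)), 1e-7)
    pw <- p$W
    gWnum <- numGrad(function(w) {
      p2 <- new.env(); p2$W <- w; p2$b <- p$b
      sum(fw(p2, x, 2L, 1L) * gy)
    }, pw)
    expect_lt(max(abs(gWnum - gr$gw)), 1e-7)
  }
  # batch normalisation backward
  bn <- nanoelast:::bnInit(2)
  bn$gamma <- runif(2, 0.5, 1.5); bn$beta <- rnorm(2)
  xb <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  fwb <- nanoelast:::bnFw(bn, xb, TRUE, 0.8)
  gyb <- array(rnorm(length(fwb$y)), dim(fwb$y))
  bb <- nanoelast:::bnBw(bn, fwb$cache, gyb)
  gXb <- numGrad(function(a) sum(nanoelast:::bnFw(bn, a, TRUE, 0.8)$y * gyb),
                 xb, 1e-5)
  expect_lt(max(abs(gXb - bb$gx)), 1e-6)
})

test_that("the generator maps 64x64 inputs to bounded 32x32 maps", {
  cfg <- ganGeneratorConfig(baseFilters = 4)
  gen <- buildGenerator(cfg, seed = 1)
  expect_length(gen$down, 5)                    # 5 down, 4 up blocks
  expect_length(gen$up, 4)
  expect_null(gen$down[[1]]$bn)                 # no BN in the initial block
  expect_false(is.null(gen$down[[2]]$bn))
  y <- predictPatches(gen, array(0, c(64, 64, 1, 2)))
  expect_equal(dim(y), c(32L, 32L, 1L, 2L))
  expect_true(all(abs(y) <= 1))                 # tanh output range
  y2 <- predictPatches(gen, array(rnorm(64 * 64 * 3), c(64, 64, 1, 3)))
  expect_true(all(is.finite(y2)) && all(abs(y2) <= 1))
})

test_that("the discriminator emits a finite validity patch map", {
  cfg <- ganGeneratorConfig(baseFilters = 4)
  disc <- buildDiscriminator(cfg, seed = 2)
  expect_length(disc$body, 4)                   # four conv blocks
  expect_equal(disc$dropoutRate, 0.25)
  expect_null(disc$body[[1]]$bn)                # initial block without BN
  withr::local_seed(3)
  fw <- nanoelast:::discForward(disc,
                                array(rnorm(64 * 64 * 2), c(64, 64, 1, 2)),
                                array(rnorm(32 * 32 * 2), c(32, 32, 1, 2)),
                                train = FALSE)
  expect_true(all(is.finite(fw$v)))
  expect_equal(dim(fw$v)[1:2], c(2L, 2L))
})

test_that("adversarial training reduces the validation error", {
  pairs <- toyPairs(32)
  sp <- splitDataset(pairs, 0.75, seed = 1)
  cfg <- ganGeneratorConfig(baseFilters = 4)
  fit <- trainGan(sp$train, cfg,
                  ganTrainConfig(batchSize = 8, epochs = 40, seed = 3),
                  valPairs = sp$validation)
  h <- fit$history
  expect_true(all(is.finite(h$dLoss)))
  expect_lt(min(h$valMae), h$valMae[1])         # best epoch beats epoch 1
  # reconstruction ablation: dropping the L1 term hurts at equal epochs
  fit0 <- trainGan(sp$train, cfg,
                   ganTrainConfig(batchSize = 8, epochs = 40, seed = 3,
                                  lossWeights = c(adversarial = 1,
                                                  reconstruction = 0)),
                   valPairs = sp$validation)
  expect_gt(min(fit0$history$valMae), min(h$valMae))
  expect_error(trainGan(list(), cfg), "empty")
})

test_that("generator checkpoints round trip through disk", {
  pairs <- toyPairs(8)
  cfg <- ganGeneratorConfig(baseFilters = 4)
  gen <- buildGenerator(cfg, seed = 9)
  d <- withr::local_tempdir()
  saveGenerator(gen, d)
  gen2 <- loadGenerator(d)
  x <- pairsToArrays(pairs)$x
  expect_equal(predictPatches(gen2, x), predictPatches(gen, x))
  expect_true(file.exists(file.path(d, "architecture.json")))
})

test_that("whole-sample prediction tiles contiguously within [0, 2] kPa", {
  em <- generateEMField("no_tumour", c(48, 48), seed = 21)
  tp <- generateTopologyField(em, seed = 22)
  img <- renderUnstainedImage(em, tp, seed = 23)
  gen <- buildGenerator(ganGeneratorConfig(baseFilters = 4), seed = 4)
  pm <- predictWholeSample(img, gen, sampleId = "S1")
  expect_s4_class(pm, "PredictionMap")
  expect_true(all(emValues(pm) >= 0 & emValues(pm) <= 2))
  inner <- emValues(pm)[17:(nrow(emValues(pm)) - 16),
                        17:(ncol(emValues(pm)) - 16)]
  expect_true(all(is.finite(inner)))            # contiguous coverage
  # overlap-averaged (stride 16) stays close to abutting tiles (stride 32)
  pm16 <- predictWholeSample(img, gen, stride = 16L, sampleId = "S1")
  both <- validMask(pm) & validMask(pm16)
  expect_lt(mean(abs(emValues(pm)[both] - emValues(pm16)[both])), 0.2)
  expect_error(predictWholeSample(
    new("MicroscopyImage", pixels = matrix(0.5, 8, 8), pixelSize = 1.625,
        magnification = 4), gen), "smaller")
})

test_that("tissue masking recovers the phantom mask and honours overrides", {
  em <- generateEMField("tumour", c(64, 64), seed = 31)
  tp <- generateTopologyField(em, seed = 32)
  mask <- nanoelast:::defaultTissueMask(c(64L, 64L))
  img <- renderUnstainedImage(em, tp, tissueMask = mask, seed = 33)
  auto <- buildTissueMask(img)
  maskCam <- nanoelast:::resampleBilinear(mask * 1, 1.25, 1.625) >= 0.5
  recall <- sum(auto & maskCam) / sum(maskCam)
  expect_gte(recall, 0.95)
  # all-background image -> empty mask
  expect_false(any(buildTissueMask(matrix(0.92, 40, 40))))
  # manual mask override is exact
  manual <- matrix(FALSE, nrow(auto), ncol(auto)); manual[1:5, ] <- TRUE
  expect_identical(buildTissueMask(img, manualMask = manual), manual)
  expect_error(buildTissueMask(img, manualMask = matrix(TRUE, 3, 3)),
               "shape mismatch")
})
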