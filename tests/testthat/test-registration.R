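test_that("NCC finds exact self-matches and rejects degenerate templates", {
  withr::local_seed(1)
  img <- matrix(runif(70 * 60), 70, 60)
  tpl <- img[21:40, 16:30]
  r <- normalizedCrossCorrelation(tpl, img)
  expect_equal(r$peak, c(21, 16))
  expect_equal(r$value, 1, tolerance = 1e-9)
  expect_true(all(r$map[!is.na(r$map)] >= -1 & r$map[!is.na(r$map)] <= 1))
  expect_error(normalizedCrossCorrelation(matrix(0.5, 10, 10), img),
               "zero variance")
  expect_error(normalizedCrossCorrelation(img, tpl), "strictly smaller")
})

test_that("NCC equals the direct definition and survives noise", {
  withr::local_seed(2)
  img <- matrix(runif(50 * 45), 50, 45)
  tpl <- img[11:26, 21:32]
  r <- normalizedCrossCorrelation(tpl, img)
  direct <- function(i, j) {
    w <- img[i:(i + 15), j:(j + 11)]
    sum((w - mean(w)) * (tpl - mean(tpl))) /
      sqrt(sum((w - mean(w))^2) * sum((tpl - mean(tpl))^2))
  }
  for (k in 1:10) {
    i <- sample(nrow(r$map), 1); j <- sample(ncol(r$map), 1)
    expect_equal(r$map[i, j], direct(i, j), tolerance = 1e-9)
  }
  # planted occluded template recovered under additive noise, 5 seeds
  for (s in 1:5) {
    withr::with_seed(s, {
      scene <- matrix(runif(120 * 120), 120, 120)
      planted <- matrix(runif(30 * 30), 30, 30)
      at <- c(sample(80, 1), sample(80, 1))
      scene[at[1]:(at[1] + 29), at[2]:(at[2] + 29)] <- planted
      noisy <- scene + matrix(rnorm(120 * 120, 0, 5 / 255), 120, 120)
      expect_equal(normalizedCrossCorrelation(planted, noisy)$peak, at)
    })
  }
})

test_that("template chains propagate the measurement point across scales", {
  t40 <- makeCantileverTemplate(40)
  t20 <- makeCantileverTemplate(20)
  t10 <- makeCantileverTemplate(10)
  t4 <- makeCantileverTemplate(4)
  # single template: identity pass-through
  expect_identical(registerTemplateChain(list(t4)), t4)
  # synthetic chain with known geometry: all templates view the same
  # physical scene centred on the bead, so the propagated 4x point must land
  # on the 4x template's own (known) point
  out <- registerTemplateChain(list(t40, t20, t10, t4))
  expect_lt(max(abs(out@measurementPoint - t4@measurementPoint)), 1.5)
  # a direct 40x -> 4x hop applies the 1/10 coordinate scaling in one step
  out2 <- registerTemplateChain(list(t40, t4))
  expect_lt(max(abs(out2@measurementPoint - t4@measurementPoint)), 1.5)
  expect_error(registerTemplateChain(list(t4, t40)), "decreasing")
})

test_that("CLAHE preserves range conventions and raises contrast", {
  withr::local_seed(3)
  expect_equal(sd(applyClahe(matrix(0.5, 64, 64), 32)), 0)
  lowc <- matrix(0.5 + 0.02 * rnorm(96 * 96), 96, 96)
  out <- applyClahe(lowc, 32)
  expect_gte(sd(out), sd(lowc))
  expect_true(is.matrix(out) && all(dim(out) == dim(lowc)))
  expect_error(applyClahe(lowc, 200), "window larger")
  # window = image size approximates global equalization (flat histogram)
  g <- applyClahe(lowc, 96)
  gn <- (sort(as.vector(g)) - min(g)) / diff(range(g))
  expect_lt(max(abs(gn - seq(0.5, length(g) - 0.5) / length(g))), 0.05)
})

test_that("resampling to the common 0.125 um grid uses the 13/10 ratios", {
  m8 <- matrix(rnorm(64), 8, 8)
  up <- resampleToCommonGrid(m8, 1.25)
  expect_equal(dim(up), c(80L, 80L))            # 8 x 8 -> 80 x 80
  expect_equal(dim(resampleToCommonGrid(matrix(0, 19, 19), 1.625)),
               c(247L, 247L))                   # 13x for camera pixels
  expect_identical(resampleToCommonGrid(m8, 0.125), m8)   # identity
  cm <- resampleToCommonGrid(matrix(2.5, 8, 8), 1.25)
  expect_lt(max(abs(cm - 2.5)), 1e-12)          # constant under bilinear
  expect_error(resampleToCommonGrid(m8, 1.3), "not commensurate")
})

test_that("EM scaling is the stated bijection with [0, 2] kPa clamping", {
  x <- seq(0, 2, by = 0.05)
  expect_equal(unscaleEM(scaleEM(x)), x)
  expect_equal(scaleEM(c(0, 1, 2)), c(-1, 0, 1))
  expect_equal(scaleEM(c(2.5, 3)), c(1, 1))     # clamp before scaling
  expect_equal(unscaleEM(scaleEM(0.7)), 0.7)
  expect_equal(scaleIntensity(c(0, 0.5, 1)), c(-1, 0, 1))
})

test_that("the sliding MI map equals brute-force recomputation exactly", {
  withr::local_seed(4)
  img <- matrix(runif(400), 20, 20)
  tpl <- img[6:13, 9:16] + 0
  res <- mutualInformationMap(tpl, img, nBins = 8, minPairs = 10)
  brute <- matrix(0, nrow(res$mi), ncol(res$mi))
  for (i in seq_len(nrow(brute))) for (j in seq_len(ncol(brute)))
    brute[i, j] <- miOracle(as.vector(img[i:(i + 7), j:(j + 7)]),
                            as.vector(tpl), 8)
  expect_equal(res$mi, brute, tolerance = 1e-12)
  expect_equal(res$argmax, c(6, 9))             # MI maximal under identity
  # invariance: a monotone nonlinear transform keeps the argmax
  res2 <- mutualInformationMap(exp(2 * tpl), img, nBins = 8, minPairs = 10)
  expect_equal(res2$argmax, c(6, 9))
  expect_error(mutualInformationMap(img, tpl), "fit inside")
})

test_that("MI of independent fields sits at the estimator's bias floor", {
  # the 32-bin histogram estimator has a positive bias of roughly
  # (nbins-1)^2 / (2 N ln 2) ~ 0.11 bits at N = 6400; independent fields
  # must sit at that floor, far below matched-signal MI
  vals <- sapply(1:3, function(s) withr::with_seed(s, {
    a <- nanoelast:::gaussSmooth(matrix(rnorm(80 * 80), 80, 80), 2)
    b <- nanoelast:::gaussSmooth(matrix(rnorm(80 * 80), 80, 80), 2)
    c(indep = miOracle(as.vector(a), as.vector(b), 32),
      self = miOracle(as.vector(a), as.vector(a), 32))
  }))
  expect_lt(median(vals["indep", ]), 0.2)
  expect_lt(median(vals["indep", ] / vals["self", ]), 0.1)
})

test_that("fine localisation is exact for planted sub-windows and falls back", {
  withr::local_seed(5)
  patchUp <- matrix(runif(140 * 140), 140, 140)
  topo <- patchUp[31:110, 21:100]
  res <- mutualInformationMap(topo, patchUp)
  expect_equal(res$argmax, c(31, 21))
  # no usable topology signal -> fallback with warning
  patch <- matrix(runif(19 * 19), 19, 19)
  topoNA <- matrix(NA_real_, 8, 8)
  expect_warning(out <- fineLocalizeArea(patch, topoNA), "falling back")
  expect_true(out$fallback)
})

test_that("training pairs have the published shapes, scaling and NaN policy", {
  withr::local_seed(6)
  patchUp <- matrix(runif(247 * 247, 0.2, 0.8), 247, 247)
  fine <- list(offset = c(84, 84), patchUp = patchUp, fallback = FALSE)
  em <- matrix(runif(64, 0, 2), 8, 8)
  tp <- extractTrainingPair(fine, em, "S001", "s1")
  expect_equal(dim(tp@imagePatch), c(64L, 64L))
  expect_equal(dim(tp@emMap), c(32L, 32L))
  expect_true(all(abs(tp@imagePatch) <= 1) && all(abs(tp@emMap) <= 1))
  expect_equal(tp@fineOffset, c(84, 84))
  # EM endpoints and clamping through the affine map
  emC <- matrix(1, 8, 8); emC[1, 1] <- 3       # out-of-range value
  tpC <- extractTrainingPair(fine, emC, "S001", "s2")
  expect_equal(tpC@emMap[32, 32], 0)           # 1 kPa -> 0
  expect_equal(max(tpC@emMap), 1)              # 3 kPa clamped to 2 -> +1
  # too many NaN cells -> site discarded
  emN <- em; emN[1:4, 1:4] <- NA               # 25% NaN
  expect_message(bad <- extractTrainingPair(fine, emN, "S001", "s3"),
                 "discarded")
  expect_null(bad)
  # a tolerable NaN fraction is imputed from the nearest valid neighbour
  emI <- em; emI[3, 5] <- NA
  tpI <- extractTrainingPair(fine, emI, "S001", "s4")
  expect_false(anyNA(tpI@emMap))
  # context exceeding the patch bounds skips the site
  expect_message(oob <- extractTrainingPair(
    list(offset = c(10, 84), patchUp = patchUp, fallback = FALSE), em),
    "skipped")
  expect_null(oob)
})

test_that("dataset splits are disjoint, exhaustive and reproducible", {
  pairs <- toyPairs(40)                        # 10 samples x 4 sites
  sp <- splitDataset(pairs, 0.8, seed = 7)
  ids <- function(x) vapply(x, function(p) p@siteId, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$validation)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$validation)), ids(pairs))
  sidsTr <- unique(vapply(sp$train, function(p) p@sampleId, character(1)))
  sidsVa <- unique(vapply(sp$validation, function(p) p@sampleId, character(1)))
  expect_length(intersect(sidsTr, sidsVa), 0)  # split by sample
  expect_length(sidsTr, 8)                     # 10 samples at 0.8 -> 8 / 2
  sp2 <- splitDataset(pairs, 0.8, seed = 7)
  expect_identical(ids(sp2$train), ids(sp$train))
  # pair-level split reproduces the 386 -> 309/77 bookkeeping
  p386 <- rep(pairs, length.out = 386)
  sp3 <- splitDataset(p386, 0.8, seed = 8, by = "pair")
  expect_lte(abs(length(sp3$train) - 309), 1)
  expect_lte(abs(length(sp3$validation) - 77), 1)
  expect_error(splitDataset(pairs, 1.2), "fraction")
  expect_error(splitDataset(pairs[1]), "at least 2")
})
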