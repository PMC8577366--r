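test_that("Hertz fitting recovers the modulus of noiseless curves", {
  for (E in c(0.2, 0.8, 1.0, 2.3)) {
    cu <- simulateForceCurve(E, noiseSd = 0)
    expect_equal(fitHertzSphere(cu), E, tolerance = 1e-6)
  }
  expect_equal(fitHertzSphere(simulateForceCurve(0, noiseSd = 0)), 0)
  expect_true(is.nan(fitHertzSphere(nanoelast:::invalidForceCurve())))
})

test_that("contact-point thresholding handles baseline-shifted curves", {
  cu <- simulateForceCurve(1, noiseSd = 0)
  # shift the contact point: prepend a flat pre-contact baseline
  shifted <- new("ForceCurve",
                 indentation = c(seq(0, 0.18, by = 0.02),
                                 cu@indentation + 0.2),
                 force = c(rep(0, 10), cu@force),
                 contactOffset = 0, valid = TRUE)
  E <- fitHertzSphere(shifted, contactThreshold = 1e-6)
  expect_equal(E, 1, tolerance = 0.05)
})

test_that("force-map processing produces EM and median-centred topology", {
  cfg <- acquisitionConfig()
  # constant-E phantom -> constant EM map
  curves <- lapply(1:64, function(i)
    simulateForceCurve(1.2, cfg, noiseSd = 0, contactOffset = 0.5))
  fm <- processForceMap(curves, cfg)
  expect_equal(max(abs(emValues(fm) - 1.2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(heights(fm))), 0)     # offsets centred on the median
  expect_error(processForceMap(curves[1:60], cfg), "expected 64")

  # planted tilted plane recovered within 1% after median centering
  slope <- c(0.12, -0.07)                    # um per grid step
  idx <- expand.grid(i = 1:8, j = 1:8)
  curves2 <- lapply(seq_len(64), function(k) {
    i <- (k - 1) %/% 8 + 1; j <- (k - 1) %% 8 + 1
    simulateForceCurve(1, cfg, noiseSd = 0,
                       contactOffset = 3 + slope[1] * i + slope[2] * j)
  })
  fm2 <- processForceMap(curves2, cfg)
  grid <- data.frame(i = rep(1:8, times = 8), j = rep(1:8, each = 8))
  fit <- lm(as.vector(heights(fm2)) ~ grid$i + grid$j)
  expect_equal(unname(coef(fit)[2]), slope[1], tolerance = 0.01)
  expect_equal(unname(coef(fit)[3]), slope[2], tolerance = 0.01)

  # NaN conservation: dropouts propagate one-for-one
  curves3 <- curves
  curves3[c(3, 17, 40)] <- list(nanoelast:::invalidForceCurve(),
                                nanoelast:::invalidForceCurve(),
                                nanoelast:::invalidForceCurve())
  fm3 <- processForceMap(curves3, cfg)
  expect_equal(sum(is.na(emValues(fm3))), 3)
  expect_equal(mean(is.na(emValues(fm3))), 3 / 64)
})

test_that("simulate -> process round trip recovers the field at grid points", {
  relRmse <- sapply(1:5, function(s) {
    em <- generateEMField("no_tumour", c(48, 48), seed = s)
    tp <- generateTopologyField(em, seed = s + 100)
    fmSim <- simulateForceMap(em, tp, c(30, 30), forceNoiseSd = 0.01,
                              seed = s + 200)
    fm <- suppressWarnings(processForceMap(fmSim$curves))
    sqrt(mean((emValues(fm) - fmSim$trueEm)^2)) / mean(fmSim$trueEm)
  })
  expect_lt(mean(relRmse), 0.02)
})

test_that("ForceMap CSV round trip preserves the grids", {
  cfg <- acquisitionConfig()
  curves <- lapply(1:64, function(i)
    simulateForceCurve(0.9, cfg, noiseSd = 0, contactOffset = i * 0.01))
  fm <- processForceMap(curves, cfg, siteId = "rt", siteCenter = c(31, 47))
  d <- withr::local_tempdir()
  writeForceMap(fm, d)
  back <- readForceMap(d)
  expect_equal(emValues(back), emValues(fm))
  expect_equal(heights(back), heights(fm))
  expect_equal(siteCenter(back), c(31, 47))
})
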