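test_that("tissue class table matches the documented stiffness groupings", {
  expect_setequal(tissueClasses(),
                  c("no_tumour", "necrotic", "fibrotic", "tumour"))
  tu <- tissueClassParams("tumour")
  expect_length(tu$means, 2)
  expect_true(all(tu$weights > 0) && abs(sum(tu$weights) - 1) < 1e-12)
  for (cl in setdiff(tissueClasses(), "tumour"))
    expect_length(tissueClassParams(cl)$means, 1)
  expect_error(tissueClassParams("adipose"), "valid classes")
})

test_that("EM fields reproduce the class marginal and are deterministic", {
  f1 <- generateEMField("no_tumour", c(64, 64), seed = 11)
  f2 <- generateEMField("no_tumour", c(64, 64), seed = 11)
  expect_identical(emValues(f1), emValues(f2))
  expect_lt(mean(emValues(f1)), 1)           # healthy liver: means up to 1 kPa
  expect_gt(mean(emValues(f1)), 0.5)
  # distributional fidelity: KS distance to the target mixture < 0.05, 3 seeds
  p <- tissueClassParams("no_tumour")
  for (s in 1:3) {
    v <- sort(as.vector(emValues(generateEMField("no_tumour", c(64, 64),
                                                 seed = s))))
    ks <- max(abs(seq_along(v) / length(v) -
                    pmixnorm(v, p$means, p$sds, p$weights)))
    expect_lt(ks, 0.05)
  }
})

test_that("tumour fields are bimodal with the published LEP/HEP peaks", {
  f <- generateEMField("tumour", c(96, 96), seed = 5)
  d <- density(as.vector(emValues(f)))
  atx <- function(x) d$y[which.min(abs(d$x - x))]
  # density peaks near 0.65 and 2.26 kPa with a dip between
  expect_gt(atx(0.65), 1.5 * atx(1.45))
  expect_gt(atx(2.26), 1.5 * atx(1.45))
})

test_that("degenerate class parameters give a constant field", {
  f <- generateEMField("flat", c(16, 16), seed = 1,
                       emParams = list(means = 0.9, sds = 0,
                                       weights = 1))
  expect_equal(max(abs(emValues(f) - 0.9)), 0)
})

test_that("topology fields carry the planted EM coupling", {
  em <- generateEMField("no_tumour", c(64, 64), seed = 2)
  flat <- generateTopologyField(em, roughness = 0, seed = 1)
  expect_equal(diff(range(heights(flat))), 0)
  planted <- nanoelast:::plantedTopologyRho(sd(emValues(em)))
  for (s in 1:3) {
    tp <- generateTopologyField(em, seed = s)
    rho <- cor(as.vector(heights(tp)), as.vector(emValues(em)),
               method = "spearman")
    expect_lt(abs(abs(rho) - planted), 0.1)  # planted coupling recovered
    expect_gte(abs(rho), 0.3)                # documented coupling floor
  }
})

test_that("rendered images are a monotone EM/topology mixture", {
  em <- generateEMField("flat", c(32, 32), seed = 1,
                        emParams = list(means = 1, sds = 0, weights = 1))
  tp <- generateTopologyField(em, roughness = 0, seed = 1)
  img <- renderUnstainedImage(em, tp, noiseSd = 0, seed = 1)
  expect_equal(diff(range(pixelValues(img))), 0)   # constant in, constant out
  # informative rendering: MI(image, EM) beats MI(image, shuffled EM)
  em2 <- generateEMField("tumour", c(64, 64), seed = 3)
  tp2 <- generateTopologyField(em2, seed = 4)
  img2 <- renderUnstainedImage(em2, tp2, seed = 5)
  iu <- nanoelast:::resampleBilinear(pixelValues(img2), 1.625, 1.25,
                                     outDim = c(64L, 64L))
  v <- as.vector(emValues(em2))
  miTrue <- miOracle(as.vector(iu), v)
  miShuf <- miOracle(as.vector(iu), sample(v))
  expect_gt(miTrue, miShuf)
  # empty tissue mask renders pure background
  img3 <- renderUnstainedImage(em, tp, noiseSd = 0,
                               tissueMask = matrix(FALSE, 32, 32), seed = 1)
  expect_lt(max(abs(pixelValues(img3) - 0.92)), 1e-12)
  expect_error(renderUnstainedImage(em, tp, noiseSd = -1), "noiseSd")
  expect_error(renderUnstainedImage(em2, tp, seed = 1), "co-registered")
})

test_that("force curves follow the Hertz sphere law and the setpoint", {
  cu0 <- simulateForceCurve(0, noiseSd = 0)
  expect_true(all(cu0@force == 0))
  cu <- simulateForceCurve(1, noiseSd = 0)
  i1 <- which.min(abs(cu@indentation - 1))
  expect_equal(cu@force[i1], 4 / 3 * (1 / 0.75) * sqrt(5), tolerance = 1e-12)
  # unit consistency at 10 random parameter sets against the scalar oracle
  withr::with_seed(42, for (k in 1:10) {
    E <- runif(1, 0.1, 3); R <- runif(1, 1, 10); nu <- runif(1, 0, 0.49)
    d <- runif(1, 0.1, 3)
    expect_equal(hertzForce(E, d, R, nu), hertzOracle(E, d, R, nu),
                 tolerance = 1e-12)
  })
  # a stiff point hits the 2 nN setpoint before 3 um
  stiff <- simulateForceCurve(5, acquisitionConfig(forceSetpoint = 2),
                              noiseSd = 0)
  expect_lt(max(stiff@indentation), 3)
  expect_true(all(stiff@force <= 2 + 1e-9))
  expect_error(simulateForceCurve(-1), "E must be")
})

test_that("force maps have the printed grid geometry and dropout behaviour", {
  em <- generateEMField("no_tumour", c(64, 64), seed = 6)
  tp <- generateTopologyField(em, seed = 7)
  fm <- simulateForceMap(em, tp, c(40, 40), seed = 8)
  expect_length(fm$curves, 64)               # 8 x 8 grid
  expect_equal(fm$pitch, 1.25)               # 10 um / 8 lateral spacing
  expect_true(all(vapply(fm$curves, function(c) c@valid, logical(1))))
  fmD <- simulateForceMap(em, tp, c(40, 40), dropoutProb = 0.5, seed = 9)
  nInvalid <- sum(!vapply(fmD$curves, function(c) c@valid, logical(1)))
  # binomial-count oracle: same generator contract, same seed
  expected <- withr::with_seed(9L, sum(runif(64) < 0.5))
  expect_identical(nInvalid, expected)
  expect_error(simulateForceMap(em, tp, c(2, 40)), "outside the field")
})

test_that("occluded FOV rendering composites the template with ground truth", {
  em <- generateEMField("no_tumour", c(200, 200), seed = 10)
  tp <- generateTopologyField(em, seed = 11)
  img <- renderUnstainedImage(em, tp, seed = 12)
  tpl <- makeCantileverTemplate(4)
  ctr <- c(125, 125)
  scene <- renderAfmFov(img, ctr, tpl, fovUm = c(220, 220), noiseSd = 0)
  expect_identical(scene$siteCenter, ctr)    # bookkeeping identity
  # fully opaque template pixels equal the template image
  tplOpaque <- new("CantileverTemplate", image = tpl@image,
                   alpha = (tpl@alpha > 0) * 1,
                   measurementPoint = tpl@measurementPoint,
                   magnification = 4)
  scene2 <- renderAfmFov(img, ctr, tplOpaque, fovUm = c(220, 220),
                         noiseSd = 0)
  t0 <- scene2$templateOrigin
  d <- dim(tpl@image)
  occ <- scene2$fov@pixels[t0[1]:(t0[1] + d[1] - 1),
                           t0[2]:(t0[2] + d[2] - 1)]
  where <- tpl@alpha > 0
  expect_equal(occ[where], tpl@image[where])
  expect_error(renderAfmFov(img, c(10, 10), tpl, fovUm = c(220, 220)),
               "too close to the border")
})

test_that("cohorts are reproducible with the documented composition", {
  co1 <- suppressWarnings(
    generateCohort(nPerClass = 1, classList = "no_tumour", seed = 4,
                   fieldShape = c(64, 64), what = c("fields", "force")))
  expect_equal(nrow(cohortRecords(co1)), 1)
  expect_gte(cohortRecords(co1)$nSites, 10)  # 10-20 force maps per sample
  co2 <- suppressWarnings(
    generateCohort(nPerClass = 1, classList = "no_tumour", seed = 4,
                   fieldShape = c(64, 64), what = c("fields", "force")))
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
  co3 <- generateCohort(nPerClass = 7, seed = 5, fieldShape = c(32, 32),
                        what = "fields")
  expect_equal(nrow(cohortRecords(co3)), 28) # 4 classes x 7
  expect_error(generateCohort(composition = integer(0)), "class list")
  expect_error(generateCohort(nPerClass = 2, classList = "stroma"),
               "unknown tissue classes")
})
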