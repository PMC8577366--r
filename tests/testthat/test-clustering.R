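test_that("distribution summaries match hand-computed moments", {
  x <- c(0, 0, 0, 2)
  s <- summarizeDistribution(x)
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 1)                        # n-1 denominator
  # adjusted Fisher-Pearson skewness, evaluated directly
  n <- 4
  g1 <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_equal(s$skewness, g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(s$skewness, e1071::skewness(x, type = 2))
  # constant distribution: zero spread and zero skewness by convention
  cs <- summarizeDistribution(rep(1.3, 50))
  expect_equal(unlist(cs[c("mean", "sd", "skewness")]),
               c(mean = 1.3, sd = 0, skewness = 0))
  sym <- withr::with_seed(1, summarizeDistribution(rnorm(20000, 1, 0.2)))
  expect_lt(abs(sym$skewness), 0.05)
  pm <- new("PredictionMap", em = matrix(1, 4, 4),
            mask = matrix(c(TRUE, rep(FALSE, 15)), 4, 4),
            pixelSize = 0.3125, sampleId = "S1")
  expect_error(summarizeDistribution(pm), "fewer than 2")
})

test_that("the gap criterion recovers planted cluster counts", {
  # three well-separated spherical blobs: k = 3 in >= 9/10 seeds
  hits <- sapply(1:10, function(s) withr::with_seed(s, {
    ctrs <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8))
    X <- do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(rnorm(30, 0, 1), 10, 3), 2, ctrs[i, ], "+")))
    selectK(X, seed = s)$k
  }))
  expect_gte(sum(hits == 3), 9)
  # a single blob collapses to k = 1
  one <- withr::with_seed(2, matrix(rnorm(60), 20, 3))
  expect_equal(selectK(one, seed = 2)$k, 1L)
  # identical rows are degenerate
  expect_equal(selectK(matrix(1, 10, 3))$k, 1L)
  expect_error(selectK(matrix(rnorm(12), 4, 3)), "kMax")
})

test_that("EM fitting of diagonal mixtures recovers planted parameters", {
  X <- withr::with_seed(11, rbind(
    cbind(rnorm(250, 0, 0.1), rnorm(250, 0, 0.1), rnorm(250, 0, 0.1)),
    cbind(rnorm(250, 1, 0.1), rnorm(250, 1, 0.1), rnorm(250, 1, 0.1))))
  m <- fitMixture(X, k = 2, seed = 1)
  expect_true(m@converged)
  ord <- order(m@means[, 1])
  expect_lt(max(abs(m@means[ord[1], ] - 0)), 0.05)
  expect_lt(max(abs(m@means[ord[2], ] - 1)), 0.05)
  expect_equal(sum(m@weights), 1)
  # independent cross-check against a reference EM implementation
  mclustBIC <- mclust::mclustBIC       # Mclust looks this up unqualified
  mc <- suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVI",
                                        verbose = FALSE))
  mcMeans <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_lt(max(abs(m@means[ord, ] - mcMeans)), 0.05)
})

test_that("k = 1 mixtures have the closed-form solution", {
  X <- withr::with_seed(12, matrix(rnorm(300, 2, 0.5), 100, 3))
  m <- fitMixture(X, k = 1, seed = 1)
  expect_equal(as.vector(m@means), colMeans(X), tolerance = 1e-8)
  # maximum-likelihood variance (n denominator) plus the regularisation floor
  mlVar <- colMeans(sweep(X, 2, colMeans(X))^2)
  expect_equal(as.vector(m@variances), mlVar + 0.01, tolerance = 1e-6)
})

test_that("duplicate points pin variances at the regularisation floor", {
  X <- matrix(1, 20, 3)
  m <- suppressWarnings(fitMixture(X, k = 2, seed = 1))
  expect_true(all(abs(m@variances - 0.01) < 1e-9))
})

test_that("EM log-likelihood is non-decreasing within every replicate", {
  X <- withr::with_seed(13, rbind(matrix(rnorm(90, 0, 0.3), 30, 3),
                                  matrix(rnorm(90, 3, 0.3), 30, 3)))
  m <- fitMixture(X, k = 2, seed = 5)
  traces <- attr(m, "logLikTrace")
  expect_gte(length(traces), 1)
  for (tr in traces) expect_true(all(diff(tr) >= -1e-8))
})

test_that("cluster naming follows majority labels with fixed tie-breaking", {
  rec <- data.frame(
    sampleId = sprintf("S%02d", 1:9),
    labels = c("tumour", "tumour", "no_tumour",
               "no_tumour", "no_tumour", "no_tumour",
               "necrotic/no_tumour", "necrotic/no_tumour", "necrotic/no_tumour"),
    mean = c(1.5, 1.6, 1.55, 0.8, 0.82, 0.78, 0.42, 0.40, 0.44),
    sd = c(0.9, 0.92, 0.88, 0.2, 0.21, 0.19, 0.15, 0.16, 0.14),
    skewness = c(0.5, 0.52, 0.48, 0, 0.01, -0.01, 0.1, 0.12, 0.08))
  model <- fitMixture(as.matrix(rec[, c("mean", "sd", "skewness")]), k = 3,
                      seed = 2)
  out <- assignAndName(model, rec)
  # the tumour-dominated cluster is named by its majority label
  expect_equal(out$predictedName[1], out$predictedName[2])
  expect_true("tumour" %in% out$predictedName)
  # a second soft cluster is distinguished with a compound name
  softNames <- unique(out$predictedName[4:9])
  expect_true(any(grepl("/", softNames)) || length(softNames) == 2)
  # posterior assignment equals brute-force density argmax on 5 points
  X <- as.matrix(rec[, c("mean", "sd", "skewness")])
  for (i in c(1, 3, 5, 7, 9)) {
    dens <- sapply(seq_len(model@k), function(j)
      model@weights[j] * prod(dnorm(X[i, ], model@means[j, ],
                                    sqrt(model@variances[j, ]))))
    expect_equal(out$cluster[i], which.max(dens))
  }
})

test_that("the scoring rule implements partial-match accuracy", {
  r1 <- data.frame(predictedName = "no_tumour",
                   labels = "necrotic/tumour/no_tumour")
  expect_equal(scoreAccuracy(r1), 1)           # partial match counts
  r2 <- data.frame(predictedName = "tumour", labels = "no_tumour")
  expect_equal(scoreAccuracy(r2), 0)
  # compound predicted names match on any token
  r3 <- data.frame(predictedName = "necrotic/no_tumour", labels = "necrotic")
  expect_equal(scoreAccuracy(r3), 1)
  # 25 of 28 correct reproduces the headline arithmetic
  r <- data.frame(predictedName = c(rep("tumour", 25), rep("tumour", 3)),
                  labels = c(rep("tumour", 25), rep("no_tumour", 3)))
  expect_equal(scoreAccuracy(r), 25 / 28)
  expect_equal(round(100 * scoreAccuracy(r), 1), 89.3)
})
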