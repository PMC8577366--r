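# Shared fixtures and independent oracles used across the suite.

# Independent histogram MI oracle (32-bin convention of the estimator),
# written against the definition rather than the C++ path.
miOracle <- function(a, b, nb = 32) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(floor((a - ra[1]) / diff(ra) * nb), nb - 1)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * nb), nb - 1)
  J <- table(factor(ia, 0:(nb - 1)), factor(ib, 0:(nb - 1))) / length(a)
  Pa <- rowSums(J); Pb <- colSums(J)
  s <- J > 0
  sum(J[s] * log2(J[s] / outer(Pa, Pb)[s]))
}

# Closed-form Hertz force written independently of the package's helper.
hertzOracle <- function(E, delta, R, nu) {
  4 / 3 * sqrt(R) * E / (1 - nu^2) * delta^1.5
}

# Mixture CDF for distribution-fidelity checks.
pmixnorm <- function(q, means, sds, w) {
  rowSums(sapply(seq_along(means),
                 function(i) w[i] * pnorm(q, means[i], sds[i])))
}

# Small deterministic cohort used by several tests.
tinyCohort <- function(seed = 3, what = c("fields", "images", "force")) {
  suppressWarnings(generateCohort(
    composition = c(no_tumour = 2, tumour = 2), seed = seed,
    fieldShape = c(64L, 64L), sitesPerSample = c(3L, 4L), what = what))
}

# Pairs with a trivially learnable mapping (EM map = smoothed central patch
# intensity), for fast optimisation tests that do not need the simulator.
toyPairs <- function(n = 32, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    z <- matrix(rnorm(64 * 64), 64, 64)
    k <- matrix(1 / 25, 5, 5)
    sm <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(z)), k)))
    img <- pmin(pmax(sm * 2, -1), 1)
    ctr <- img[17:48, 17:48]
    em <- (ctr[seq(1, 32, 1), seq(1, 32, 1)] + 1)   # in [0, 2]
    new("TrainingPair", imagePatch = img, emMap = scaleEM(em),
        sampleId = sprintf("S%02d", (i - 1) %/% 4 + 1),
        siteId = sprintf("t%03d", i), fineOffset = c(1, 1))
  }))
}
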