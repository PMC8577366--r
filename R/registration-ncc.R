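#' Normalized cross-correlation template matching
#'
#' Computes the normalized cross-correlation (NCC) between a template and
#' every fully contained placement of it inside an image, returning the
#' correlation map and the location of its maximum. The numerator is computed
#' by FFT cross-correlation and the per-window normalisation from integral
#' images, so large whole-sample scenes stay fast; results equal the direct
#' definition up to floating-point error. Windows with (numerically) zero
#' variance are excluded (NA). Ties at the maximum break to the smallest row,
#' then smallest column.
#'
#' @param template numeric matrix, strictly smaller than \code{image}, with
#'   nonzero variance.
#' @param image numeric matrix.
#' @return a list: \code{map} ((M-m+1) x (N-n+1) matrix of correlations in
#'   [-1, 1], NA where excluded), \code{peak} c(row, col) 1-based placement
#'   of the template top-left at the maximum, and \code{value} the peak
#'   correlation.
#' @export
normalizedCrossCorrelation <- function(template, image) {
  m <- nrow(template); n <- ncol(template)
  M <- nrow(image); N <- ncol(image)
  if (m >= M || n >= N) stop("template must be strictly smaller than image")
  tz <- template - mean(template)
  tnorm <- sqrt(sum(tz^2))
  if (tnorm < 1e-12 * m * n || tnorm == 0)
    stop("template has zero variance")
  P <- stats::nextn(M, c(2, 3, 5))
  Q <- stats::nextn(N, c(2, 3, 5))
  ip <- matrix(0, P, Q); ip[1:M, 1:N] <- image
  tp <- matrix(0, P, Q); tp[1:m, 1:n] <- tz
  num <- Re(stats::fft(stats::fft(ip) * Conj(stats::fft(tp)),
                       inverse = TRUE)) / (P * Q)
  num <- num[1:(M - m + 1), 1:(N - n + 1), drop = FALSE]
  # windowed sums via integral images
  integ <- function(a) {
    S <- matrix(0, M + 1, N + 1)
    S[-1, -1] <- t(apply(apply(a, 2, cumsum), 1, cumsum))
    S
  }
  S1 <- integ(image)
  S2 <- integ(image^2)
  winSum <- function(S) {
    S[(m + 1):(M + 1), (n + 1):(N + 1)] - S[1:(M - m + 1), (n + 1):(N + 1)] -
      S[(m + 1):(M + 1), 1:(N - n + 1)] + S[1:(M - m + 1), 1:(N - n + 1)]
  }
  ws <- winSum(S1)
  wvar <- winSum(S2) - ws^2 / (m * n)
  wvar[wvar < 0] <- 0
  den <- sqrt(wvar) * tnorm
  eps <- 1e-10 * m * n * max(abs(image))^2
  map <- num / den
  map[den <= eps] <- NA_real_
  map <- pmin(pmax(map, -1), 1)
  if (all(is.na(map))) stop("all windows excluded (zero variance everywhere)")
  pk <- argmaxRC(map, tol = 1e-9)
  list(map = map, peak = pk, value = map[pk[1], pk[2]])
}

#' Propagate the measurement point down a magnification chain
#'
#' Sequentially registers cantilever template images taken at decreasing
#' magnification, propagating the known measurement point (given in the
#' highest-magnification template) down to the lowest-magnification (4x)
#' template with magnification-ratio coordinate scaling. Each higher-mag
#' template is downscaled by the magnification ratio and located in the next
#' template by NCC; a peak below \code{threshold} aborts with the offending
#' pair named.
#'
#' @param templates list of \linkS4class{CantileverTemplate}, ordered by
#'   strictly decreasing magnification; the first carries the known
#'   measurement point.
#' @param threshold minimum acceptable NCC peak.
#' @return a \linkS4class{CantileverTemplate}: the last template with the
#'   propagated measurement point.
#' @export
registerTemplateChain <- function(templates, threshold = 0.5) {
  if (length(templates) < 1) stop("need at least one template")
  if (length(templates) == 1) return(templates[[1]])
  mags <- vapply(templates, function(t) t@magnification, numeric(1))
  if (any(diff(mags) >= 0))
    stop("templates must be ordered by strictly decreasing magnification")
  point <- templates[[1]]@measurementPoint
  for (i in seq_len(length(templates) - 1)) {
    hi <- templates[[i]]; lo <- templates[[i + 1]]
    ratio <- hi@magnification / lo@magnification
    small <- resampleBilinear(hi@image, 1, ratio)
    res <- normalizedCrossCorrelation(small, lo@image)
    if (res$value < threshold)
      stop(sprintf("registration failed between %gx and %gx templates (peak %.3f < %.2f)",
                   hi@magnification, lo@magnification, res$value, threshold))
    # centre-aligned pixel scaling, then the NCC placement offset
    point <- (point - 0.5) / ratio + 0.5 + (res$peak - 1)
  }
  out <- templates[[length(templates)]]
  new("CantileverTemplate", image = out@image, alpha = out@alpha,
      measurementPoint = point, magnification = out@magnification)
}

#' Coarse localisation of a measurement site on the whole-sample image
#'
#' Two-stage NCC localisation: the 4x cantilever template is located in the
#' AFM field-of-view image (giving the occluded measurement point in FOV
#' coordinates), then the FOV is located on the whole-sample image; composing
#' the two offsets gives the site centre in whole-image coordinates.
#'
#' @param afmFov FOV \linkS4class{MicroscopyImage} (cantilever in view).
#' @param template4x \linkS4class{CantileverTemplate} at the image
#'   magnification with known measurement point.
#' @param wholeImage whole-sample \linkS4class{MicroscopyImage}.
#' @return a list: \code{centerPx} c(row, col) site centre in whole-image
#'   pixels, \code{centerUm} in um, \code{pointInFov}, and the two NCC peak
#'   values \code{peakTemplate}, \code{peakFov}.
#' @export
coarseLocalizeSite <- function(afmFov, template4x, wholeImage) {
  if (abs(afmFov@pixelSize - wholeImage@pixelSize) > 1e-9)
    stop("FOV and whole image must share the object-plane pixel size")
  r1 <- normalizedCrossCorrelation(template4x@image, afmFov@pixels)
  pointInFov <- (r1$peak - 1) + template4x@measurementPoint
  if (identical(dim(afmFov@pixels), dim(wholeImage@pixels))) {
    off <- c(0, 0); pk2 <- 1
  } else {
    r2 <- normalizedCrossCorrelation(afmFov@pixels, wholeImage@pixels)
    off <- r2$peak - 1
    pk2 <- r2$value
  }
  centerPx <- off + pointInFov
  # centerPx is a 1-based pixel index; its physical position is (i - 0.5) * ps
  list(centerPx = centerPx, centerUm = (centerPx - 0.5) * wholeImage@pixelSize,
       pointInFov = pointInFov, peakTemplate = r1$value, peakFov = pk2)
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE contrast enhancement with a given tile window size in pixels
#' (default 32, the enhancement used before fine registration and
#' prediction). Thin wrapper over \code{EBImage::clahe} with the tile grid
#' derived from the window size; output is rescaled to the input's intensity
#' range so range conventions are preserved. Deterministic.
#'
#' @param image numeric matrix in [0, 1] or a \linkS4class{MicroscopyImage}.
#' @param window tile window size in pixels (>= 2, at most the image size).
#' @return same type as the input, contrast enhanced.
#' @export
applyClahe <- function(image, window = 32) {
  mat <- if (is(image, "MicroscopyImage")) image@pixels else image
  if (window < 2) stop("window must be >= 2")
  if (window > min(dim(mat))) stop("window larger than the image")
  rng <- range(mat)
  if (rng[2] - rng[1] < 1e-12) return(image)    # constant in, constant out
  nx <- max(1L, as.integer(round(ncol(mat) / window)))
  ny <- max(1L, as.integer(round(nrow(mat) / window)))
  x <- (mat - rng[1]) / (rng[2] - rng[1])
  if (nx < 2 || ny < 2) {
    # window covers the (nearly) whole image: global histogram equalization
    r <- rank(x, ties.method = "average")
    out <- matrix((r - 0.5) / length(x), nrow(x), ncol(x))
  } else {
    eq <- EBImage::clahe(EBImage::Image(t(x)), nx = nx, ny = ny,
                         bins = 256, limit = 2, keep = TRUE)
    out <- t(EBImage::imageData(eq))
  }
  out <- pmin(pmax(out, 0), 1) * (rng[2] - rng[1]) + rng[1]
  if (is(image, "MicroscopyImage"))
    new("MicroscopyImage", pixels = out, pixelSize = image@pixelSize,
        magnification = image@magnification)
  else out
}
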