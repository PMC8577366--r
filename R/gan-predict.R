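#' Whole-sample elastic-modulus prediction
#'
#' Runs the trained generator over a whole-sample unstained image: the image
#' is resampled to the 0.3125 um output pixel size of the training patches,
#' tiled with overlapping 64 x 64 input patches at the given stride, and each
#' 32 x 32 output is placed at its patch centre (the central 10 um of the
#' 20 um input). Stride 32 tiles the output exactly without overlap; smaller
#' strides overlap-average. Predictions are unscaled to kPa (bounded in
#' [0, 2]) and masked by the tissue mask plus the border where no full input
#' patch exists. Preprocessing must match training: by default the intensity
#' scale is left as-is (the simulator's illumination is calibrated, and
#' absolute intensity carries the stiffness signal); set
#' \code{enhance = TRUE} to apply CLAHE with a 32 pixel window, the setting
#' intended for real camera data with uneven illumination.
#'
#' @param image whole-sample \linkS4class{MicroscopyImage}.
#' @param gen trained generator.
#' @param stride tile stride in output pixels (default 32).
#' @param enhance apply CLAHE (32 px window) after resampling.
#' @param mask optional manual tissue mask (logical matrix at the *input*
#'   image resolution); NULL uses \code{\link{buildTissueMask}}.
#' @param outputPixel output pixel size, um.
#' @param sampleId recorded in the result.
#' @param batch patches per generator call.
#' @return a \linkS4class{PredictionMap}.
#' @export
predictWholeSample <- function(image, gen, stride = 32L, mask = NULL,
                               outputPixel = 0.3125, sampleId = "S000",
                               batch = 64L, enhance = FALSE) {
  up <- resampleBilinear(image@pixels, image@pixelSize, outputPixel)
  if (any(dim(up) < 64))
    stop("image smaller than one 64 x 64 input patch after resampling")
  if (enhance) up <- applyClahe(up, 32)
  xs <- scaleIntensity(up)
  d <- dim(xs)
  r0s <- unique(c(seq(1L, d[1] - 63L, by = stride), d[1] - 63L))
  c0s <- unique(c(seq(1L, d[2] - 63L, by = stride), d[2] - 63L))
  tiles <- expand.grid(r = r0s, c = c0s)
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (b0 in seq(1, nrow(tiles), by = batch)) {
    bi <- b0:min(b0 + batch - 1, nrow(tiles))
    xb <- array(0, c(64, 64, 1, length(bi)))
    for (k in seq_along(bi))
      xb[, , 1, k] <- xs[tiles$r[bi[k]]:(tiles$r[bi[k]] + 63L),
                         tiles$c[bi[k]]:(tiles$c[bi[k]] + 63L)]
    yb <- predictPatches(gen, xb)
    for (k in seq_along(bi)) {
      # the 32 x 32 output covers the central half of the input patch
      rr <- (tiles$r[bi[k]] + 16L):(tiles$r[bi[k]] + 47L)
      cc <- (tiles$c[bi[k]] + 16L):(tiles$c[bi[k]] + 47L)
      acc[rr, cc] <- acc[rr, cc] + unscaleEM(yb[, , 1, k])
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
  }
  em <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  if (is.null(mask)) mask <- buildTissueMask(image)
  if (!identical(dim(mask), dim(image@pixels)))
    stop("manual mask shape mismatch with the input image")
  maskUp <- resampleBilinear(mask * 1, image@pixelSize, outputPixel,
                             outDim = d) >= 0.5
  valid <- maskUp & cnt > 0
  em[!valid] <- 0
  new("PredictionMap", em = pmin(pmax(em, 0), 2), mask = valid,
      pixelSize = outputPixel, sampleId = sampleId)
}

#' Automatic tissue mask
#'
#' Builds the validity mask that excludes background and unreliable regions
#' from whole-sample predictions. Automatic masking combines an Otsu
#' intensity threshold (the unstained section is darker than the surrounding
#' buffer background) with a local-variance focus proxy: tissue pixels whose
#' local variance falls below the \code{varPercentile}-th percentile of the
#' image-wide local variance (a noise-dominated floor set by the flat buffer
#' background) are treated as featureless -- out of focus, fluid bubbles or
#' glue render as flat as the empty buffer. A supplied manual mask overrides
#' the automatic rule entirely.
#'
#' @param image \linkS4class{MicroscopyImage} (or intensity matrix in [0, 1]).
#' @param manualMask optional logical matrix of the same shape; returned
#'   as-is (after a shape check).
#' @param varWindow local-variance window in pixels.
#' @param varPercentile image-wide local-variance percentile used as the
#'   featurelessness threshold.
#' @return logical matrix, TRUE = valid tissue.
#' @export
buildTissueMask <- function(image, manualMask = NULL, varWindow = 7L,
                            varPercentile = 0.1) {
  mat <- if (is(image, "MicroscopyImage")) image@pixels else image
  if (!is.null(manualMask)) {
    if (!identical(dim(manualMask), dim(mat)))
      stop("manual mask shape mismatch")
    return(manualMask)
  }
  rng <- range(mat)
  if (rng[2] - rng[1] < 1e-9) return(matrix(FALSE, nrow(mat), ncol(mat)))
  thr <- EBImage::otsu(EBImage::Image(t(mat)), range = rng)
  tissue <- mat < thr                       # tissue is darker than background
  if (!any(tissue) || all(tissue)) return(tissue)
  # local variance as focus proxy, calibrated against the flat background
  box <- matrix(1 / varWindow^2, varWindow, varWindow)
  f <- function(m) t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), box)))
  lv <- pmax(f(mat^2) - f(mat)^2, 0)
  vthr <- stats::quantile(lv, varPercentile)
  tissue & lv >= vthr
}
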