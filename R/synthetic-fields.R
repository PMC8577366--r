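#' Generate a class-conditional elastic-modulus field
#'
#' Simulates a spatially correlated per-pixel EM field whose marginal
#' distribution follows the tissue class's (mixture-of-)Gaussian parameters.
#' A white-noise field is smoothed to the requested correlation length and
#' then histogram-matched to a sample drawn from the class mixture, so the
#' marginal is exact (up to sampling) while spatial structure has the stated
#' scale; values are clamped at 0 kPa.
#'
#' @param classLabel tissue class name (see \code{\link{tissueClasses}}), or
#'   any label when \code{emParams} is supplied.
#' @param shape field dimensions in pixels, c(rows, cols); at least 16 x 16.
#' @param pixelSize pixel size in um (default 1.25, the force-map pitch).
#' @param correlationLength spatial correlation length in um. The default,
#'   2 um, puts tissue texture at the cellular/collagen-bundle scale, finer
#'   than the 10 um measurement window so that structure is localisable.
#' @param emParams optional override of the class distribution, a list with
#'   \code{means}, \code{sds}, \code{weights} (kPa); defaults to
#'   \code{tissueClassParams(classLabel)}.
#' @param seed integer seed; the field is deterministic given it.
#' @return an \linkS4class{EMField}.
#' @examples
#' f <- generateEMField("no_tumour", shape = c(32, 32), seed = 1)
#' mean(emValues(f))
#' @export
generateEMField <- function(classLabel, shape = c(128L, 128L),
                            pixelSize = 1.25, correlationLength = 2,
                            emParams = NULL, seed = 1L) {
  if (any(shape < 16)) stop("shape must be at least 16 x 16")
  if (correlationLength <= 0) stop("correlationLength must be > 0")
  if (is.null(emParams)) emParams <- tissueClassParams(classLabel)
  else validateEmParams(emParams)
  vals <- withSeed(seed, {
    z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    zs <- gaussSmooth(z, correlationLength / pixelSize)
    n <- prod(shape)
    comp <- sample.int(length(emParams$means), n, replace = TRUE,
                       prob = emParams$weights)
    target <- sort(stats::rnorm(n, emParams$means[comp], emParams$sds[comp]))
    out <- matrix(0, shape[1], shape[2])
    out[order(zs)] <- target
    out
  })
  new("EMField", values = pmax(vals, 0), pixelSize = pixelSize,
      classLabel = as.character(classLabel))
}

#' Generate a topology field coupled to an EM field
#'
#' Simulates the tissue surface relief used as the fine-registration signal.
#' Stiffer tissue resists compression during sectioning and stands proud of
#' softer regions, so heights couple to the *absolute* elastic modulus
#' through a fixed affine standardisation shared by all samples:
#' \code{z_em = clamp((em - emCenter) / emScale, +/- 2.5)} and
#' \code{h = roughness * (coupling * z_em + sqrt(1 - coupling^2) * z_noise)}
#' with an independent smoothed noise field \code{z_noise}. The planted
#' EM-height correlation for a sample whose EM standard deviation is
#' \code{s} is therefore \code{coupling * (s / emScale) /
#' sqrt(coupling^2 * (s / emScale)^2 + 1 - coupling^2)} -- about 0.4 for
#' healthy liver at the defaults, above the 0.3 coupling floor the
#' registration stage assumes, and higher for heterogeneous (tumour) tissue.
#'
#' @param emField an \linkS4class{EMField}.
#' @param roughness height scale in um (default 1.5); 0 gives a flat surface.
#' @param coupling mixing weight of the EM-coupled component, in [0, 1].
#' @param emCenter,emScale fixed EM standardisation (kPa), shared across
#'   samples so that height carries absolute stiffness information.
#' @param retractionLimit cantilever retraction limit in um; heights are
#'   clamped to +/- this value.
#' @param seed integer seed.
#' @return a \linkS4class{TopologyField} with the same shape and pixel size.
#' @export
generateTopologyField <- function(emField, roughness = 1.5, coupling = 0.8,
                                  emCenter = 1.0, emScale = 0.6,
                                  retractionLimit = 15, seed = 1L) {
  if (roughness < 0) stop("roughness must be >= 0")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  v <- emField@values
  # salt the stream so sharing a seed number with the EM field cannot
  # correlate the relief noise with the field's own noise
  h <- withSeed(childSeed(seed, 7717L), {
    zem <- pmin(pmax((v - emCenter) / emScale, -2.5), 2.5)
    zn <- gaussSmooth(matrix(stats::rnorm(length(v)), nrow(v), ncol(v)), 1.6)
    zn <- (zn - mean(zn)) / stats::sd(zn)
    roughness * (coupling * zem + sqrt(1 - coupling^2) * zn)
  })
  h <- pmin(pmax(h, -retractionLimit), retractionLimit)
  new("TopologyField", heights = h, pixelSize = emField@pixelSize,
      retractionLimit = retractionLimit)
}

# planted EM-height correlation implied by the coupling model
plantedTopologyRho <- function(emSd, coupling = 0.8, emScale = 0.6) {
  s <- coupling * emSd / emScale
  s / sqrt(s^2 + 1 - coupling^2)
}

#' Render an unstained brightfield image of a tissue phantom
#'
#' Produces the low-resolution grayscale image of the unstained section that
#' the prediction network consumes. Tissue intensity is a fixed monotone
#' (logistic) function of a stated linear mixture of the standardised EM and
#' topology fields -- brightfield contrast of unstained tissue is dominated by
#' surface relief and scattering, so topology carries most of the weight
#' (default 0.7 vs 0.3 for EM) -- plus additive Gaussian noise, resampled to
#' the 1.625 um camera grid. Pixels outside the tissue mask are rendered at a
#' bright background level, as for a section surrounded by clear buffer.
#'
#' @param emField an \linkS4class{EMField}.
#' @param topology a \linkS4class{TopologyField} on the same grid.
#' @param noiseSd additive intensity noise SD (image range is [0, 1]);
#'   default 0.004, about one grey level of an 8-bit camera.
#' @param emWeight weight of EM in the intensity mixture (topology gets
#'   \code{1 - emWeight}).
#' @param tissueMask logical matrix on the field grid, TRUE = tissue; NULL
#'   (default) renders everything as tissue.
#' @param backgroundLevel background intensity in [0, 1].
#' @param cameraPixel camera pixel size in um.
#' @param magnification nominal magnification recorded in the image.
#' @param seed integer seed (noise).
#' @return a \linkS4class{MicroscopyImage} at the camera pixel size.
#' @export
renderUnstainedImage <- function(emField, topology, noiseSd = 0.004,
                                 emWeight = 0.3, tissueMask = NULL,
                                 backgroundLevel = 0.92, cameraPixel = 1.625,
                                 magnification = 4, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!identical(dim(emField@values), dim(topology@heights)))
    stop("emField and topology are not co-registered (different grids)")
  if (abs(emField@pixelSize - topology@pixelSize) > 1e-9)
    stop("emField and topology differ in pixel size")
  # fixed standardisations so intensity encodes *absolute* EM and height
  emN <- pmin(pmax(emField@values / 2, 0), 1) - 0.5          # [0,2] kPa -> [-.5,.5]
  tpN <- topology@heights / 6                                # um -> ~[-.5,.5]
  mix <- emWeight * 2 * emN + (1 - emWeight) * 2 * tpN
  tissue <- stats::plogis(1.5 * mix) * 0.7 + 0.1             # monotone squash into [0.1, 0.8]
  if (!is.null(tissueMask)) {
    if (!identical(dim(tissueMask), dim(tissue)))
      stop("tissueMask shape mismatch")
    tissue[!tissueMask] <- backgroundLevel
  }
  img <- resampleBilinear(tissue, emField@pixelSize, cameraPixel)
  img <- withSeed(childSeed(seed, 3313L),
                  img + matrix(stats::rnorm(length(img), 0, noiseSd),
                               nrow(img), ncol(img)))
  new("MicroscopyImage", pixels = pmin(pmax(img, 0), 1),
      pixelSize = cameraPixel, magnification = magnification)
}

# default elliptical tissue mask covering most of a field
defaultTissueMask <- function(shape, fill = 0.92) {
  r <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2 * fill)
  c <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2 * fill)
  outer(r^2, c^2, "+") <= 1
}
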