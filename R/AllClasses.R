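#' @import methods
NULL

#' Acquisition geometry and cantilever parameters
#'
#' Holds the physical parameters of the AFM force-mapping acquisition: a
#' tipless cantilever carrying a borosilicate bead of radius \code{beadRadius}
#' (default 5 um, i.e. a 10 um diameter bead) with spring constant
#' \code{springConstant} = 0.08 N/m indents the section up to
#' \code{maxIndentation} = 3 um at \code{indentationSpeed} = 1 um/s, stopping
#' early once \code{forceSetpoint} (nN) is reached. Each measurement site is a
#' \code{gridN} x \code{gridN} grid of force-indentation curves over a square
#' area of side \code{mapSide} um, giving a lateral pitch of
#' \code{mapSide / gridN} (1.25 um at the defaults). \code{cameraPixel} is the
#' object-plane pixel size of the 4x brightfield camera (1.625 um).
#'
#' @slot beadRadius bead radius in um.
#' @slot springConstant cantilever spring constant in N/m.
#' @slot maxIndentation maximum indentation depth in um.
#' @slot indentationSpeed indentation speed in um/s.
#' @slot forceSetpoint force setpoint in nN (within the 2-5 nN working range).
#' @slot poissonRatio Poisson ratio of the tissue (0.5 = incompressible).
#' @slot gridN points per side of the force-map grid.
#' @slot mapSide side length of the measurement area in um.
#' @slot cameraPixel camera pixel size at the object plane in um.
#' @slot afmGridPitch lateral spacing of force-map points in um.
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(beadRadius = "numeric", springConstant = "numeric",
                 maxIndentation = "numeric", indentationSpeed = "numeric",
                 forceSetpoint = "numeric", poissonRatio = "numeric",
                 gridN = "integer", mapSide = "numeric",
                 cameraPixel = "numeric", afmGridPitch = "numeric"))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  pos <- c(beadRadius = object@beadRadius, springConstant = object@springConstant,
           maxIndentation = object@maxIndentation,
           indentationSpeed = object@indentationSpeed,
           forceSetpoint = object@forceSetpoint, mapSide = object@mapSide,
           cameraPixel = object@cameraPixel, afmGridPitch = object@afmGridPitch)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("not strictly positive:", paste(bad, collapse = ", ")))
  if (object@gridN < 2L) msg <- c(msg, "gridN must be >= 2")
  if (object@poissonRatio < 0 || object@poissonRatio >= 1)
    msg <- c(msg, "poissonRatio must be in [0, 1)")
  if (abs(object@mapSide / object@gridN - object@afmGridPitch) > 1e-9)
    msg <- c(msg, "afmGridPitch must equal mapSide / gridN")
  if (length(msg)) msg else TRUE
})

#' Whole-sample or field-of-view grayscale microscopy image
#'
#' Single-channel intensity image in [0, 1] with a physical pixel size at the
#' object plane. Pixel (i, j) is centred at ((i - 0.5), (j - 0.5)) *
#' \code{pixelSize} um from the image top-left corner (row-major, origin
#' top-left).
#'
#' @slot pixels numeric matrix of intensities in [0, 1].
#' @slot pixelSize object-plane pixel size in um.
#' @slot magnification nominal objective magnification.
#' @exportClass MicroscopyImage
setClass("MicroscopyImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 magnification = "numeric"))

setValidity("MicroscopyImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0")
  TRUE
})

#' Ground-truth elastic-modulus field
#'
#' Per-pixel elastic modulus (kPa) over a tissue section, the quantity the
#' style-transfer network is trained to infer. Values are non-negative and
#' finite; \code{classLabel} records the generating tissue class (possibly a
#' compound such as \code{"necrotic/no_tumour"} for mixed-pathology sections).
#'
#' @slot values numeric matrix of EM in kPa.
#' @slot pixelSize pixel size in um.
#' @slot classLabel tissue class label string.
#' @exportClass EMField
setClass("EMField",
  representation(values = "matrix", pixelSize = "numeric",
                 classLabel = "character"))

setValidity("EMField", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (any(object@values < 0)) return("values must be >= 0")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0")
  TRUE
})

#' Tissue surface topology field
#'
#' Relative axial surface heights (um) of the section, the structural signal
#' used for fine mutual-information registration. Heights are relative offsets
#' and may be negative; they must stay within the cantilever retraction limit.
#'
#' @slot heights numeric matrix of heights in um.
#' @slot pixelSize pixel size in um.
#' @slot retractionLimit maximum |height| representable by the cantilever (um).
#' @exportClass TopologyField
setClass("TopologyField",
  representation(heights = "matrix", pixelSize = "numeric",
                 retractionLimit = "numeric"))

setValidity("TopologyField", function(object) {
  if (any(!is.finite(object@heights))) return("heights must be finite")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0")
  if (any(abs(object@heights) > object@retractionLimit))
    return("heights exceed the retraction limit")
  TRUE
})

#' A single force-indentation curve
#'
#' Indentation depth (um, non-decreasing from 0) and measured force (nN) for
#' one point of a force map, together with the axial contact-point offset used
#' to estimate tissue topology. Curves that could not be captured (e.g. the
#' surface was beyond the cantilever retraction range) are flagged invalid and
#' carry no samples, mirroring the NaN bookkeeping of the acquisition software.
#'
#' @slot indentation numeric vector, um.
#' @slot force numeric vector, nN.
#' @slot contactOffset axial contact-point offset in um.
#' @slot valid logical flag.
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(indentation = "numeric", force = "numeric",
                 contactOffset = "numeric", valid = "logical"))

setValidity("ForceCurve", function(object) {
  if (length(object@indentation) != length(object@force))
    return("indentation and force lengths differ")
  if (!object@valid && length(object@force) > 0)
    return("invalid curves carry no force samples")
  if (object@valid) {
    if (length(object@indentation) == 0) return("valid curve has no samples")
    if (is.unsorted(object@indentation)) return("indentation must be non-decreasing")
    if (object@indentation[1] < 0) return("indentation starts below 0")
  }
  TRUE
})

#' Processed force map: EM and topology grids for one measurement site
#'
#' @slot em gridN x gridN matrix of elastic moduli in kPa (NaN where a curve
#'   was invalid).
#' @slot topology gridN x gridN matrix of relative heights in um (median
#'   centred; NaN where a curve was invalid).
#' @slot siteCenter site centre on the whole-sample image in um (NA until the
#'   site has been registered).
#' @slot pitch lateral grid spacing in um.
#' @slot siteId site identifier.
#' @exportClass ForceMap
setClass("ForceMap",
  representation(em = "matrix", topology = "matrix", siteCenter = "numeric",
                 pitch = "numeric", siteId = "character"))

setValidity("ForceMap", function(object) {
  if (!identical(dim(object@em), dim(object@topology)))
    return("em and topology must have the same shape")
  if (any(object@em[!is.na(object@em)] < 0)) return("non-NaN em must be >= 0")
  if (!is.finite(object@pitch) || object@pitch <= 0) return("pitch must be > 0")
  if (length(object@siteCenter) != 2) return("siteCenter must have length 2")
  TRUE
})

#' Cantilever template image with known measurement point
#'
#' A grayscale template of the AFM cantilever assembly (with the bead in
#' focus) and the pixel coordinates of its tissue contact point, used for
#' template-matching localisation of the occluded measurement area.
#'
#' @slot image numeric intensity matrix in [0, 1].
#' @slot alpha opacity matrix in [0, 1] (1 = fully occluding).
#' @slot measurementPoint (row, col) pixel coordinates of the contact point.
#' @slot magnification objective magnification the template was taken at.
#' @exportClass CantileverTemplate
setClass("CantileverTemplate",
  representation(image = "matrix", alpha = "matrix",
                 measurementPoint = "numeric", magnification = "numeric"))

setValidity("CantileverTemplate", function(object) {
  p <- object@measurementPoint
  if (length(p) != 2) return("measurementPoint must be (row, col)")
  if (any(p < 0.5) || p[1] > nrow(object@image) + 0.5 ||
      p[2] > ncol(object@image) + 0.5)
    return("measurementPoint outside image bounds")
  if (!identical(dim(object@image), dim(object@alpha)))
    return("image and alpha must have the same shape")
  TRUE
})

#' Registered image / EM-map training pair
#'
#' A finely registered 20 um x 20 um unstained-image patch (64 x 64) and its
#' 10 um x 10 um EM map (32 x 32), both affinely scaled to [-1, 1] (EM clamped
#' to [0, 2] kPa before scaling) for the tanh output of the generator.
#'
#' @slot imagePatch 64 x 64 matrix in [-1, 1].
#' @slot emMap 32 x 32 matrix in [-1, 1].
#' @slot sampleId sample identifier.
#' @slot siteId site identifier.
#' @slot fineOffset (row, col) of the fine-registered area within the search
#'   patch, in 0.125 um pixels.
#' @exportClass TrainingPair
setClass("TrainingPair",
  representation(imagePatch = "matrix", emMap = "matrix",
                 sampleId = "character", siteId = "character",
                 fineOffset = "numeric"))

setValidity("TrainingPair", function(object) {
  if (!identical(dim(object@imagePatch), c(64L, 64L)))
    return("imagePatch must be 64 x 64")
  if (!identical(dim(object@emMap), c(32L, 32L)))
    return("emMap must be 32 x 32")
  rng <- range(object@imagePatch, object@emMap)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    return("arrays must lie within [-1, 1]")
  TRUE
})

#' Whole-sample elastic-modulus prediction
#'
#' Per-pixel inferred EM (kPa, bounded in [0, 2]) at the network output
#' resolution, with a validity mask excluding background, artefacts and the
#' border where no full input patch exists.
#'
#' @slot em numeric matrix of EM in kPa.
#' @slot mask logical matrix, TRUE where the prediction is valid tissue.
#' @slot pixelSize output pixel size in um.
#' @slot sampleId sample identifier.
#' @exportClass PredictionMap
setClass("PredictionMap",
  representation(em = "matrix", mask = "matrix", pixelSize = "numeric",
                 sampleId = "character"))

setValidity("PredictionMap", function(object) {
  if (!identical(dim(object@em), dim(object@mask)))
    return("em and mask must have the same shape")
  if (!is.logical(object@mask)) return("mask must be logical")
  v <- object@em[object@mask]
  if (length(v) && (any(!is.finite(v)) || any(v < -1e-9) || any(v > 2 + 1e-9)))
    return("masked-valid EM values must lie within [0, 2] kPa")
  TRUE
})

#' Diagonal-covariance Gaussian mixture model
#'
#' Result of expectation-maximisation fitting of a k-component Gaussian
#' mixture with diagonal covariance matrices to the distribution-summary
#' features (mean, SD, skewness).
#'
#' @slot k number of components.
#' @slot weights mixing proportions (sum to 1).
#' @slot means k x d matrix of component means.
#' @slot variances k x d matrix of per-dimension variances (>= the
#'   regularisation floor).
#' @slot logLik final log-likelihood.
#' @slot converged logical convergence flag.
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(k = "integer", weights = "numeric", means = "matrix",
                 variances = "matrix", logLik = "numeric",
                 converged = "logical"))

setValidity("MixtureModel", function(object) {
  if (length(object@weights) != object@k) return("weights length != k")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (any(object@weights <= 0)) return("weights must be > 0")
  if (nrow(object@means) != object@k || nrow(object@variances) != object@k)
    return("means/variances must have k rows")
  TRUE
})

#' Synthetic tissue cohort
#'
#' A collection of simulated tissue samples: per-sample ground-truth EM and
#' topology fields, rendered unstained whole-sample images and AFM force maps
#' at randomly placed measurement sites, plus a records table mirroring a
#' clinical manifest (sample id, pathology labels, number of sites).
#'
#' @slot samples named list of per-sample data (see \code{generateCohort}).
#' @slot records data.frame manifest with one row per sample.
#' @slot seed integer seed the cohort was generated from.
#' @exportClass TissueCohort
setClass("TissueCohort",
  representation(samples = "list", records = "data.frame", seed = "integer"))

setValidity("TissueCohort", function(object) {
  if (nrow(object@records) != length(object@samples))
    return("records and samples disagree in length")
  TRUE
})
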