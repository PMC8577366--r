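#' Tissue classes and their elastic-modulus distributions
#'
#' The four pathology classes of the liver cohort and the parameters of their
#' per-pixel elastic-modulus (EM) distributions, in kPa. Healthy ("no tumour")
#' and necrotic tissue are unimodal and soft (means well below ~1 kPa, widths
#' of hundreds of pascals), necrotic being the softest because it lacks the
#' fibrous proteins that confer bulk stiffness. Fibrotic tissue is unimodal
#' and distinctly stiffer. Metastatic tumour tissue is bimodal: a lower
#' elasticity peak (LEP) from highly motile cancer cells at 0.65 +/- 0.13 kPa
#' and a higher elasticity peak (HEP) from the stiffening extracellular matrix
#' at 2.26 +/- 0.60 kPa, mixed equally.
#'
#' @param name one of \code{"no_tumour"}, \code{"necrotic"},
#'   \code{"fibrotic"}, \code{"tumour"}.
#' @return \code{tissueClasses()} returns the class names;
#'   \code{tissueClassParams(name)} returns a list with elements
#'   \code{means}, \code{sds} (kPa) and \code{weights}.
#' @examples
#' tissueClasses()
#' tissueClassParams("tumour")
#' @export
tissueClasses <- function() c("no_tumour", "necrotic", "fibrotic", "tumour")

.tissueClassTable <- list(
  no_tumour = list(means = 0.8,  sds = 0.2,  weights = 1),
  necrotic  = list(means = 0.4,  sds = 0.15, weights = 1),
  fibrotic  = list(means = 1.4,  sds = 0.3,  weights = 1),
  tumour    = list(means = c(0.65, 2.26), sds = c(0.13, 0.60),
                   weights = c(0.5, 0.5))
)

#' @rdname tissueClasses
#' @export
tissueClassParams <- function(name) {
  if (length(name) != 1 || !name %in% tissueClasses())
    stop("unknown tissue class '", paste(name, collapse = ","),
         "'; valid classes: ", paste(tissueClasses(), collapse = ", "))
  p <- .tissueClassTable[[name]]
  validateEmParams(p)
  p
}

# check a class parameter list (possibly user-supplied)
validateEmParams <- function(p) {
  stopifnot(is.list(p), all(c("means", "sds", "weights") %in% names(p)))
  k <- length(p$means)
  if (length(p$sds) != k || length(p$weights) != k)
    stop("means, sds and weights must have equal length")
  if (any(p$means <= 0) || any(p$sds < 0)) stop("means must be > 0, sds >= 0")
  if (any(p$weights <= 0) || abs(sum(p$weights) - 1) > 1e-9)
    stop("weights must be positive and sum to 1")
  invisible(p)
}

#' Acquisition configuration constructor
#'
#' Builds an \linkS4class{AcquisitionConfig} with the measurement defaults of
#' the force-mapping protocol: 10 um diameter borosilicate bead (radius 5 um),
#' spring constant 0.08 N/m, 3.0 um maximum indentation at 1.0 um/s with a
#' force setpoint inside the 2-5 nN working range, 8 x 8 curves over a
#' 10 um x 10 um area (1.25 um pitch) and a 1.625 um object-plane camera pixel
#' at 4x magnification. The Poisson ratio defaults to 0.5 (incompressible
#' tissue), the usual convention for Hertz fits of soft hydrated samples.
#'
#' @param beadRadius bead radius, um.
#' @param springConstant cantilever spring constant, N/m.
#' @param maxIndentation maximum indentation depth, um.
#' @param indentationSpeed indentation speed, um/s.
#' @param forceSetpoint force setpoint, nN.
#' @param poissonRatio Poisson ratio.
#' @param gridN grid points per side.
#' @param mapSide measurement-area side, um.
#' @param cameraPixel camera pixel size at the object plane, um.
#' @return an \linkS4class{AcquisitionConfig}.
#' @examples
#' cfg <- acquisitionConfig()
#' cfg@afmGridPitch   # 1.25 um
#' @export
acquisitionConfig <- function(beadRadius = 5, springConstant = 0.08,
                              maxIndentation = 3.0, indentationSpeed = 1.0,
                              forceSetpoint = 4, poissonRatio = 0.5,
                              gridN = 8L, mapSide = 10,
                              cameraPixel = 1.625) {
  new("AcquisitionConfig", beadRadius = beadRadius,
      springConstant = springConstant, maxIndentation = maxIndentation,
      indentationSpeed = indentationSpeed, forceSetpoint = forceSetpoint,
      poissonRatio = poissonRatio, gridN = as.integer(gridN),
      mapSide = mapSide, cameraPixel = cameraPixel,
      afmGridPitch = mapSide / gridN)
}
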