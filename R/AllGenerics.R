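#' @title Accessor generics
#' @description Accessors for the package's S4 data classes.
#' @param object an object of one of the package classes.
#' @return The slot contents (see the individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("emValues", function(object) standardGeneric("emValues"))

#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(object) standardGeneric("pixelValues"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("siteCenter", function(object) standardGeneric("siteCenter"))

#' @rdname accessors
#' @export
setGeneric("cohortRecords", function(object) standardGeneric("cohortRecords"))

#' @rdname accessors
#' @export
setGeneric("cohortSamples", function(object) standardGeneric("cohortSamples"))

#' Summarise an elastic-modulus distribution
#'
#' Computes the three shape parameters used for predictive clustering of a
#' sample's EM distribution: the mean (overall stiffness, kPa), the standard
#' deviation (heterogeneity, kPa, n-1 denominator) and the adjusted
#' Fisher-Pearson skewness (tailedness, dimensionless; 0 by convention when
#' the SD is 0).
#'
#' @param object a \linkS4class{PredictionMap}, \linkS4class{EMField} or
#'   numeric vector of EM values.
#' @param ... unused.
#' @return a data.frame with columns \code{mean}, \code{sd}, \code{skewness}
#'   and \code{nPixels}.
#' @export
setGeneric("summarizeDistribution",
           function(object, ...) standardGeneric("summarizeDistribution"))
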