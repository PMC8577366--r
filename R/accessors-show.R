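#' @rdname accessors
#' @aliases emValues,EMField-method
setMethod("emValues", "EMField", function(object) object@values)

#' @rdname accessors
#' @aliases emValues,ForceMap-method
setMethod("emValues", "ForceMap", function(object) object@em)

#' @rdname accessors
#' @aliases emValues,PredictionMap-method
setMethod("emValues", "PredictionMap", function(object) object@em)

#' @rdname accessors
#' @aliases heights,TopologyField-method
setMethod("heights", "TopologyField", function(object) object@heights)

#' @rdname accessors
#' @aliases heights,ForceMap-method
setMethod("heights", "ForceMap", function(object) object@topology)

#' @rdname accessors
#' @aliases pixelValues,MicroscopyImage-method
setMethod("pixelValues", "MicroscopyImage", function(object) object@pixels)

#' @rdname accessors
#' @aliases pixelSize,MicroscopyImage-method
setMethod("pixelSize", "MicroscopyImage", function(object) object@pixelSize)

#' @rdname accessors
#' @aliases pixelSize,EMField-method
setMethod("pixelSize", "EMField", function(object) object@pixelSize)

#' @rdname accessors
#' @aliases pixelSize,TopologyField-method
setMethod("pixelSize", "TopologyField", function(object) object@pixelSize)

#' @rdname accessors
#' @aliases pixelSize,PredictionMap-method
setMethod("pixelSize", "PredictionMap", function(object) object@pixelSize)

#' @rdname accessors
#' @aliases classLabel,EMField-method
setMethod("classLabel", "EMField", function(object) object@classLabel)

#' @rdname accessors
#' @aliases validMask,PredictionMap-method
setMethod("validMask", "PredictionMap", function(object) object@mask)

#' @rdname accessors
#' @aliases siteCenter,ForceMap-method
setMethod("siteCenter", "ForceMap", function(object) object@siteCenter)

#' @rdname accessors
#' @aliases cohortRecords,TissueCohort-method
setMethod("cohortRecords", "TissueCohort", function(object) object@records)

#' @rdname accessors
#' @aliases cohortSamples,TissueCohort-method
setMethod("cohortSamples", "TissueCohort", function(object) object@samples)

setMethod("show", "MicroscopyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MicroscopyImage: %d x %d px, %.4g um/px (%.2f x %.2f um), %gx\n",
              d[1], d[2], object@pixelSize, d[1] * object@pixelSize,
              d[2] * object@pixelSize, object@magnification))
})

setMethod("show", "EMField", function(object) {
  d <- dim(object@values)
  cat(sprintf("EMField [%s]: %d x %d px at %.4g um/px; EM %.3g-%.3g kPa (mean %.3g)\n",
              object@classLabel, d[1], d[2], object@pixelSize,
              min(object@values), max(object@values), mean(object@values)))
})

setMethod("show", "TopologyField", function(object) {
  d <- dim(object@heights)
  cat(sprintf("TopologyField: %d x %d px at %.4g um/px; height %.3g-%.3g um\n",
              d[1], d[2], object@pixelSize, min(object@heights),
              max(object@heights)))
})

setMethod("show", "ForceCurve", function(object) {
  if (object@valid)
    cat(sprintf("ForceCurve: %d samples, max indentation %.3g um, max force %.3g nN\n",
                length(object@force), max(object@indentation), max(object@force)))
  else cat("ForceCurve: invalid (no samples)\n")
})

setMethod("show", "ForceMap", function(object) {
  d <- dim(object@em)
  cat(sprintf("ForceMap %s: %d x %d grid, pitch %.3g um, %d NaN; EM mean %.3g kPa\n",
              object@siteId, d[1], d[2], object@pitch, sum(is.na(object@em)),
              mean(object@em, na.rm = TRUE)))
})

setMethod("show", "CantileverTemplate", function(object) {
  d <- dim(object@image)
  cat(sprintf("CantileverTemplate: %d x %d px at %gx, measurement point (%.1f, %.1f)\n",
              d[1], d[2], object@magnification, object@measurementPoint[1],
              object@measurementPoint[2]))
})

setMethod("show", "TrainingPair", function(object) {
  cat(sprintf("TrainingPair %s/%s: image 64x64, EM 32x32 (scaled to [-1, 1])\n",
              object@sampleId, object@siteId))
})

setMethod("show", "PredictionMap", function(object) {
  d <- dim(object@em)
  v <- object@em[object@mask]
  cat(sprintf("PredictionMap %s: %d x %d px at %.4g um/px, %.1f%% valid; EM mean %.3g kPa\n",
              object@sampleId, d[1], d[2], object@pixelSize,
              100 * mean(object@mask), if (length(v)) mean(v) else NA))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: %d diagonal Gaussian components, logLik %.3f%s\n",
              object@k, object@logLik,
              if (object@converged) "" else " (not converged)"))
  m <- round(object@means, 3)
  for (i in seq_len(object@k))
    cat(sprintf("  comp %d: w=%.3f mean=(%s)\n", i, object@weights[i],
                paste(m[i, ], collapse = ", ")))
})

setMethod("show", "TissueCohort", function(object) {
  cat(sprintf("TissueCohort: %d samples (seed %d)\n", length(object@samples),
              object@seed))
  print(table(object@records$labels))
})
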