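#' Accessor generics
#'
#' Small accessor family for the package's S4 objects: the metric scale of a
#' calibration or report, the object class and bounding box of a detection,
#' and the measurement table of a tank report.
#'
#' @param object an S4 object of this package.
#' @return the slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scaleCmPerPx", function(object) standardGeneric("scaleCmPerPx"))

#' @rdname accessors
#' @export
setGeneric("objectClass", function(object) standardGeneric("objectClass"))

#' @rdname accessors
#' @export
setGeneric("bbox", function(object) standardGeneric("bbox"))

#' @rdname accessors
#' @export
setGeneric("maskOf", function(object) standardGeneric("maskOf"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("totalBiomassKg", function(object) standardGeneric("totalBiomassKg"))

#' @rdname accessors
#' @export
setMethod("scaleCmPerPx", "CalibrationResult", function(object) object@scaleCmPerPx)

#' @rdname accessors
#' @export
setMethod("scaleCmPerPx", "TankReport", function(object) object@scaleCmPerPx)

#' @rdname accessors
#' @export
setMethod("objectClass", "Detection", function(object) object@objectClass)

#' @rdname accessors
#' @export
setMethod("bbox", "Detection", function(object) object@bbox)

#' @rdname accessors
#' @export
setMethod("maskOf", "Detection", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("measurements", "TankReport", function(object) object@measurements)

#' @rdname accessors
#' @export
setMethod("totalBiomassKg", "TankReport", function(object) object@totalBiomassKg)

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px, scale %.5f cm/px, %d fish, seed %d\n",
              object@imageShape[1], object@imageShape[2], object@scaleTrue,
              nrow(object@fish), object@seed))
  cat(sprintf("  reference: %.4f cm diameter at (%.1f, %.1f)\n",
              object@referenceDiameterCm, object@referenceCenter[1],
              object@referenceCenter[2]))
})

setMethod("show", "GroundTruth", function(object) {
  cls <- vapply(object@objects, `[[`, character(1), "class")
  cat(sprintf("GroundTruth: %d objects (%d fish, %d reference), scale %.5f cm/px\n",
              length(cls), sum(cls == "fish"), sum(cls == "reference"),
              object@scaleTrue))
})

setMethod("show", "Detection", function(object) {
  flags <- c(if (object@partial) "partial", if (object@merged) "merged")
  cat(sprintf("Detection <%s>: area %d px, bbox [%s), circ %.3f, elong %.2f%s\n",
              object@objectClass, sum(object@mask),
              paste(object@bbox, collapse = ","), object@circularity,
              object@elongation,
              if (length(flags)) paste0(" [", paste(flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %.6f cm/px (reference %.4f cm = %.2f px, circ %.3f)\n",
              object@scaleCmPerPx, object@referenceDiameterCm,
              object@referenceDiameterPx, object@circularity))
})

setMethod("show", "FishMeasurement", function(object) {
  cat(sprintf("FishMeasurement #%d: length %.2f cm, width %.2f cm (%.0f deg)\n",
              object@objectId, object@lengthCm, object@widthCm,
              object@orientationDeg))
})

setMethod("show", "BiomassModel", function(object) {
  if (object@type == "baseline") {
    cat(sprintf("BiomassModel <baseline>: W = %.5g * L^%.4f * W^%.4f (g)\n",
                exp(object@baseline[1]), object@baseline[2], object@baseline[3]))
  } else {
    cat(sprintf("BiomassModel <mlp>: %s, %s, %s\n",
                paste(object@architecture, collapse = "-"), object@activation,
                if (object@trained) "trained" else "untrained"))
  }
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: train R2 %.5f (RMSE %.2f g, n=%d); test R2 %.5f (RMSE %.2f g, n=%d)\n",
              object@trainR2, object@trainRmseG, object@nTrain,
              object@testR2, object@testRmseG, object@nTest))
})

setMethod("show", "TankReport", function(object) {
  cat(sprintf("TankReport [%s]: %d fish, total biomass %.3f kg%s (scale %.5f cm/px)\n",
              object@sourceImageId, object@fishCount, object@totalBiomassKg,
              if (is.na(object@densityKgPerM2)) ""
              else sprintf(", density %.4f kg/m2", object@densityKgPerM2),
              object@scaleCmPerPx))
  print(utils::head(object@measurements, 10))
})

setMethod("show", "PairedTestResult", function(object) {
  cat(sprintf("Paired t test: mean diff %.4f +/- %.4f, t = %.4f, df = %g, p = %.4g\n",
              object@meanDifference, object@semDifference, object@tStatistic,
              object@degreesOfFreedom, object@pValue))
})

setMethod("show", "TwoSampleTestResult", function(object) {
  cat(sprintf("Two-sample t test (%s): mean diff %.4f, t = %.4f, df = %.2f, p = %.4g\n",
              object@method, object@meanDifference, object@tStatistic,
              object@degreesOfFreedom, object@pValue))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary: n = %d, mean %.4f +/- %.4f (SEM), gainers %.2f%%\n",
              object@n, object@mean, object@sem, object@gainerPercent))
})
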