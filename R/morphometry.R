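# Phase 3b: metric body measurements of each framed fish.

#' Measure a fish from its mask and the scene calibration
#'
#' Body length and width are the major and minor extents of the
#' minimum-area rotated rectangle of the mask (computed by rotating
#' calipers over the convex hull of the pixel centres, with a +1 px
#' footprint correction per side), converted to cm with the calibration
#' scale. The rotated rectangle makes the measurement independent of fish
#' orientation; an axis-aligned box would overestimate length by up to
#' sqrt(2).
#'
#' @param fish a [Detection-class] of class \code{"fish"}, not flagged
#'   partial or merged.
#' @param calibration a [CalibrationResult-class] computed on the same
#'   (resized) image.
#' @param objectId integer identifier to carry into the measurement.
#' @param minPixels masks smaller than this raise a degenerate-mask error.
#' @return a [FishMeasurement-class].
#' @section Errors: partial or merged fish raise a typed
#'   \code{measurementSkipped} condition (truncated or fused silhouettes
#'   cannot yield a valid length); undersized masks raise
#'   \code{degenerateMask}.
#' @export
measureFish <- function(fish, calibration, objectId = NA_integer_,
                        minPixels = 20) {
  stopifnot(is(fish, "Detection"), is(calibration, "CalibrationResult"))
  if (fish@objectClass != "fish")
    stop("detection is not a fish", call. = FALSE)
  if (fish@partial)
    measurementSkipped("fish touches the image border; a truncated mask cannot yield a valid length")
  if (fish@merged)
    measurementSkipped("blob exceeds single-fish bounds (likely overlapping fish)")
  if (sum(fish@mask) < minPixels)
    degenerateMaskError(sprintf("mask has fewer than %d pixels", minPixels))
  r <- minAreaRect(maskPoints(fish@mask))
  corr <- extentCorrections(r$major, r$minor)
  majorPx <- r$major + corr[["major"]]
  minorPx <- r$minor + corr[["minor"]]
  s <- calibration@scaleCmPerPx
  new("FishMeasurement", objectId = as.integer(objectId),
      lengthCm = majorPx * s, widthCm = minorPx * s,
      bbox = fish@bbox, orientationDeg = r$angleDeg %% 180,
      partial = FALSE)
}
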