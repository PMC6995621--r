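# Phase 3a: metric self-calibration from the framed reference object.

#' Derive the metric scale from the segmented reference circle
#'
#' The reference object (a white 3-D printed hemisphere of known diameter,
#' 4.2680 cm by default) appears as a circle in a top-view image. Its mask
#' pixel count A yields the equivalent-area diameter \eqn{2\sqrt{A/\pi}} in
#' pixels, and the scale is the true diameter divided by that pixel
#' diameter. The equivalent-area estimator is robust to 1-px boundary
#' noise; a bounding-box diameter is recorded alongside as a diagnostic.
#'
#' A single isotropic scale is assumed (top-down camera, flat tank bottom);
#' no 3-D camera model or refraction correction is applied.
#'
#' @param reference a [Detection-class] of class \code{"reference"}.
#' @param referenceDiameterCm true diameter of the reference in cm.
#' @param circularityMin masks less circular than this are rejected with a
#'   calibration-failure error, signalling that no usable reference exists.
#' @return a [CalibrationResult-class].
#' @examples
#' det <- segmentScene(renderScene(SceneSpec(imageShape = c(256L, 256L),
#'                                           scaleTrue = 0.05))$image)
#' calibrateFromReference(det[[1]])
#' @export
calibrateFromReference <- function(reference, referenceDiameterCm = 4.2680,
                                   circularityMin = 0.85) {
  stopifnot(is(reference, "Detection"))
  if (reference@objectClass != "reference")
    stop("detection is not a reference object", call. = FALSE)
  a <- sum(reference@mask)
  if (a == 0L) calibrationError("reference mask is empty")
  circ <- maskShapeScores(reference@mask)$circularity
  if (circ < circularityMin)
    calibrationError(sprintf(
      "reference mask circularity %.3f below %.3f: no usable reference object; place the calibration hemisphere fully in view and retake the photo",
      circ, circularityMin))
  dPx <- 2 * sqrt(a / pi)
  bb <- reference@bbox
  new("CalibrationResult",
      scaleCmPerPx = referenceDiameterCm / dPx,
      referenceDiameterPx = dPx,
      bboxDiameterPx = mean(c(bb[3] - bb[1], bb[4] - bb[2])),
      circularity = circ,
      referenceDiameterCm = referenceDiameterCm)
}
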