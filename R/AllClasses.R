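#' @import methods
NULL

#' Parametric description of a synthetic top-view tank scene
#'
#' A \code{SceneSpec} fully determines one rendered scene: image geometry,
#' background grey level and noise, the true metric scale, the circular
#' reference object, and a table of fish silhouettes. Together with its
#' \code{seed} it is a pure, reproducible recipe; see [renderScene()].
#'
#' Positions are continuous pixel coordinates \code{(row, col)} with the
#' origin at the top-left image corner, so the centre of the 1-based matrix
#' pixel \code{[r, c]} lies at \code{(r - 0.5, c - 0.5)}. Bounding boxes
#' everywhere in the package are 0-based half-open \code{(row0, col0, row1,
#' col1)}.
#'
#' @slot imageShape integer(2), image size in pixels (rows, cols).
#' @slot backgroundIntensity mean background grey level in [0, 1].
#' @slot backgroundNoiseSd sd of additive Gaussian pixel noise.
#' @slot scaleTrue true metric scale, cm per pixel (> 0).
#' @slot referenceDiameterCm true diameter of the reference circle in cm.
#' @slot referenceCenter numeric(2), reference centre (row, col) in pixels.
#' @slot referenceIntensity grey level of the (white) reference object.
#' @slot fish data.frame of fish silhouettes, one row per fish, with columns
#'   \code{length_cm}, \code{width_cm}, \code{row}, \code{col},
#'   \code{orientation_deg} (major-axis angle in [0, 180)), \code{intensity}
#'   and \code{taper} (0 = pure ellipse, 1 = fully tapered tail).
#' @slot allowOverlap logical; if FALSE, rendering rejects overlapping masks.
#' @slot seed integer RNG seed used for the pixel noise.
#'
#' @seealso [SceneSpec()], [randomSceneSpec()], [renderScene()]
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  imageShape = "integer",
  backgroundIntensity = "numeric",
  backgroundNoiseSd = "numeric",
  scaleTrue = "numeric",
  referenceDiameterCm = "numeric",
  referenceCenter = "numeric",
  referenceIntensity = "numeric",
  fish = "data.frame",
  allowOverlap = "logical",
  seed = "integer"
))

.fishCols <- c("length_cm", "width_cm", "row", "col", "orientation_deg",
               "intensity", "taper")

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (object@scaleTrue <= 0) msg <- c(msg, "scaleTrue must be > 0")
  if (object@referenceDiameterCm <= 0)
    msg <- c(msg, "referenceDiameterCm must be > 0")
  if (object@backgroundNoiseSd < 0)
    msg <- c(msg, "backgroundNoiseSd must be >= 0")
  f <- object@fish
  if (nrow(f) > 0) {
    if (!all(.fishCols %in% names(f)))
      msg <- c(msg, paste("fish table needs columns:",
                          paste(.fishCols, collapse = ", ")))
    else {
      if (any(f$length_cm <= f$width_cm) || any(f$width_cm <= 0))
        msg <- c(msg, "each fish needs length_cm > width_cm > 0")
      if (any(f$intensity < 0 | f$intensity > 1))
        msg <- c(msg, "fish intensity must lie in [0, 1]")
      if (any(f$taper < 0 | f$taper > 1))
        msg <- c(msg, "fish taper must lie in [0, 1]")
      if (any(abs(f$intensity - object@backgroundIntensity) < 0.05))
        msg <- c(msg, "fish intensity must differ from background by >= 0.05")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Exact annotations of a rendered synthetic scene
#'
#' Ground truth produced by [renderScene()]: one record per drawn object
#' (fish or reference) holding the exact binary mask (recorded before noise),
#' the tight 0-based half-open bounding box, and the true metric dimensions.
#' Fish additionally carry a true weight from the package's default
#' allometric relationship ([defaultAllometricWeight()]), making the object
#' an oracle for the detection, calibration, morphometry and biomass phases.
#'
#' @slot objects list of records; each has \code{class} ("fish" or
#'   "reference"), \code{mask} (logical matrix of the full image), \code{bbox}
#'   (integer(4), 0-based half-open), \code{length_cm}, \code{width_cm} and,
#'   for fish, \code{weight_g}.
#' @slot scaleTrue the scene's true cm-per-pixel scale.
#'
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  objects = "list",
  scaleTrue = "numeric"
))

#' One segmented object in a tank image
#'
#' The unit result of scene segmentation: a connected binary mask, its tight
#' 0-based half-open bounding box, a class decided by shape scoring
#' (circularity for the reference object, elongation for fish), a heuristic
#' confidence, and the \code{partial} / \code{merged} quality flags used to
#' exclude unmeasurable fish from morphometry.
#'
#' @slot objectClass "fish" or "reference".
#' @slot mask logical matrix, same shape as the segmented image.
#' @slot bbox integer(4), 0-based half-open (row0, col0, row1, col1).
#' @slot confidence heuristic detection confidence in [0, 1].
#' @slot circularity 4 * pi * A / P^2 of the mask (1 for a perfect disc).
#' @slot elongation major/minor extent ratio of the minimum-area rectangle.
#' @slot partial TRUE when the mask touches the image border.
#' @slot merged TRUE when the blob exceeds configured single-fish bounds.
#'
#' @exportClass Detection
setClass("Detection", representation(
  objectClass = "character",
  mask = "matrix",
  bbox = "integer",
  confidence = "numeric",
  circularity = "numeric",
  elongation = "numeric",
  partial = "logical",
  merged = "logical"
))

setValidity("Detection", function(object) {
  msg <- character()
  if (!object@objectClass %in% c("fish", "reference"))
    msg <- c(msg, "objectClass must be 'fish' or 'reference'")
  if (length(object@bbox) != 4L) msg <- c(msg, "bbox must have length 4")
  if (object@confidence < 0 || object@confidence > 1)
    msg <- c(msg, "confidence must lie in [0, 1]")
  if (!is.na(object@elongation) && object@elongation < 1 - 1e-9)
    msg <- c(msg, "elongation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Configuration of the classical scene detector
#'
#' Thresholds for the default (classical) detection backend: background-level
#' estimation by the image median, Otsu contrast thresholding of the absolute
#' deviation image, connected components, and shape-score classification.
#' A learned detector can be substituted by setting \code{backend = "plugin"}
#' and supplying a function \code{image -> list of Detection} in
#' \code{plugin}.
#'
#' @slot resizeTargetPx target for the shorter image side (default 1024).
#' @slot minObjectAreaPx components smaller than this are discarded.
#' @slot contrastMethod thresholding method; currently "otsu".
#' @slot circularityMin minimum circularity to classify as reference.
#' @slot elongationMin minimum elongation to classify as fish.
#' @slot elongationMax fish blobs beyond this are flagged \code{merged}.
#' @slot maxFishAreaPx fish blobs beyond this area are flagged \code{merged}.
#' @slot backend "classical" or "plugin".
#' @slot plugin plugin detector function, or NULL.
#'
#' @seealso [DetectorConfig()], [segmentScene()]
#' @exportClass DetectorConfig
setClass("DetectorConfig", representation(
  resizeTargetPx = "integer",
  minObjectAreaPx = "numeric",
  contrastMethod = "character",
  circularityMin = "numeric",
  elongationMin = "numeric",
  elongationMax = "numeric",
  maxFishAreaPx = "numeric",
  backend = "character",
  plugin = "ANY"
))

setValidity("DetectorConfig", function(object) {
  msg <- character()
  if (object@resizeTargetPx < 1L) msg <- c(msg, "resizeTargetPx must be >= 1")
  if (object@circularityMin <= 0 || object@circularityMin > 1.2)
    msg <- c(msg, "circularityMin out of range")
  if (object@elongationMin < 1) msg <- c(msg, "elongationMin must be >= 1")
  if (!object@backend %in% c("classical", "plugin"))
    msg <- c(msg, "backend must be 'classical' or 'plugin'")
  if (object@backend == "plugin" && !is.function(object@plugin))
    msg <- c(msg, "plugin backend requires a function in slot 'plugin'")
  if (length(msg)) msg else TRUE
})

#' Metric self-calibration from the reference object
#'
#' The cm-per-pixel scale derived from the segmented reference circle: the
#' mask's pixel count A gives an equivalent-area diameter 2 * sqrt(A / pi),
#' and the scale is the known true diameter divided by that pixel diameter.
#' A bounding-box based diameter is kept alongside as a diagnostic.
#'
#' @slot scaleCmPerPx derived scale in cm per pixel (> 0).
#' @slot referenceDiameterPx equivalent-area diameter of the mask in pixels.
#' @slot bboxDiameterPx mean of the mask bounding-box height and width.
#' @slot circularity circularity of the reference mask.
#' @slot referenceDiameterCm the true diameter used (default 4.2680 cm).
#'
#' @seealso [calibrateFromReference()]
#' @exportClass CalibrationResult
setClass("CalibrationResult", representation(
  scaleCmPerPx = "numeric",
  referenceDiameterPx = "numeric",
  bboxDiameterPx = "numeric",
  circularity = "numeric",
  referenceDiameterCm = "numeric"
))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (object@scaleCmPerPx <= 0) msg <- c(msg, "scaleCmPerPx must be > 0")
  rel <- abs(object@scaleCmPerPx * object@referenceDiameterPx -
             object@referenceDiameterCm) / object@referenceDiameterCm
  if (rel > 1e-9)
    msg <- c(msg, "scaleCmPerPx * referenceDiameterPx must equal referenceDiameterCm")
  if (length(msg)) msg else TRUE
})

#' Metric body measurements of one fish
#'
#' Length (major axis of the top-view silhouette) and width (minor axis) in
#' cm, obtained from the minimum-area rotated rectangle of the fish mask and
#' the scene calibration. Fish flagged partial or merged are never measured.
#'
#' @slot objectId integer identifier assigned by the pipeline.
#' @slot lengthCm body length in cm (major extent).
#' @slot widthCm body width in cm (minor extent).
#' @slot bbox integer(4), 0-based half-open box of the mask.
#' @slot orientationDeg major-axis angle in [0, 180) degrees.
#' @slot partial always FALSE for a measured fish (kept for the report row).
#'
#' @seealso [measureFish()]
#' @exportClass FishMeasurement
setClass("FishMeasurement", representation(
  objectId = "integer",
  lengthCm = "numeric",
  widthCm = "numeric",
  bbox = "integer",
  orientationDeg = "numeric",
  partial = "logical"
))

setValidity("FishMeasurement", function(object) {
  if (object@lengthCm < object@widthCm || object@widthCm <= 0)
    "lengthCm >= widthCm > 0 required" else TRUE
})

#' The dimensions-to-weight regressor
#'
#' Either a nine-layer fully connected network (layer widths counted as
#' input(2) -> 64 -> 64 -> 32 -> 32 -> 16 -> 16 -> 8 -> output(1), ReLU
#' hidden activations, linear output) trained on standardized inputs and
#' standardized log-weight, or a closed-form allometric power-law baseline
#' W = alpha * L^beta * W^gamma. Both predict individual weight in grams
#' from body length and width in cm through [predictWeight()].
#'
#' @slot type "mlp" or "baseline".
#' @slot architecture integer vector of layer widths (9 entries for the MLP).
#' @slot activation hidden activation name ("relu").
#' @slot weights list of weight matrices, one per connection.
#' @slot biases list of bias vectors, one per connection.
#' @slot xCenter,xScale per-feature standardization of (length, width).
#' @slot yCenter,yScale standardization of log(weight).
#' @slot baseline numeric(3): (log_alpha, beta, gamma) from the log-log
#'   least-squares fit, used for baseline prediction and as fallback.
#' @slot trainingRange 2x2 matrix, min/max of training length and width (cm);
#'   inputs outside it by more than 25\% trigger an extrapolation warning.
#' @slot trained logical.
#' @slot metadata list: optimizer, learning rate, batch size, epochs run,
#'   seed, split fraction.
#'
#' @seealso [fitBiomassMlp()], [allometricBiomassModel()], [predictWeight()]
#' @exportClass BiomassModel
setClass("BiomassModel", representation(
  type = "character",
  architecture = "integer",
  activation = "character",
  weights = "list",
  biases = "list",
  xCenter = "numeric",
  xScale = "numeric",
  yCenter = "numeric",
  yScale = "numeric",
  baseline = "numeric",
  trainingRange = "matrix",
  trained = "logical",
  metadata = "list"
))

setValidity("BiomassModel", function(object) {
  msg <- character()
  if (!object@type %in% c("mlp", "baseline"))
    msg <- c(msg, "type must be 'mlp' or 'baseline'")
  if (object@type == "mlp" && object@trained) {
    if (length(object@architecture) != 9L)
      msg <- c(msg, "MLP architecture must list exactly 9 layer widths")
    if (any(object@xScale <= 0) || any(object@yScale <= 0))
      msg <- c(msg, "standardization scales must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Fit diagnostics of a trained biomass regressor
#'
#' @slot trainR2,testR2 coefficient of determination on the gram scale.
#' @slot trainRmseG,testRmseG root-mean-square error in grams.
#' @slot lossTrace per-epoch mean training loss (standardized log-weight MSE).
#' @slot nTrain,nTest split sizes.
#'
#' @exportClass FitReport
setClass("FitReport", representation(
  trainR2 = "numeric",
  testR2 = "numeric",
  trainRmseG = "numeric",
  testRmseG = "numeric",
  lossTrace = "numeric",
  nTrain = "integer",
  nTest = "integer"
))

#' Pipeline configuration
#'
#' @slot detector a [DetectorConfig-class].
#' @slot referenceDiameterCm true reference diameter (default 4.2680 cm).
#' @slot tankFloorAreaM2 tank floor area in m^2 used for stocking density;
#'   \code{NA} disables the density column.
#' @slot minFishPx minimum mask pixel count for a measurable fish.
#'
#' @seealso [PipelineConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  detector = "DetectorConfig",
  referenceDiameterCm = "numeric",
  tankFloorAreaM2 = "numeric",
  minFishPx = "numeric"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@referenceDiameterCm <= 0)
    msg <- c(msg, "referenceDiameterCm must be > 0")
  if (!is.na(object@tankFloorAreaM2) && object@tankFloorAreaM2 <= 0)
    msg <- c(msg, "tankFloorAreaM2 must be > 0 when given")
  if (length(msg)) msg else TRUE
})

#' Per-tank measurement and biomass report
#'
#' The pipeline's output table: one row per detected fish (id, length, width,
#' predicted weight, partial flag; measurements are \code{NA} for partial or
#' merged fish) plus tank-level totals. Fish ids are consecutive integers
#' from 1, ordered by bounding-box top-left corner.
#'
#' @slot measurements data.frame with columns \code{fish_id},
#'   \code{length_cm}, \code{width_cm}, \code{weight_g}, \code{partial}.
#' @slot fishCount number of measurable (non-partial, non-merged) fish.
#' @slot totalBiomassKg sum of predicted weights over measurable fish, in kg.
#' @slot densityKgPerM2 stocking density, or NA when no floor area is set.
#' @slot scaleCmPerPx calibration scale used.
#' @slot sourceImageId identifier of the analysed image.
#'
#' @seealso [runPipeline()], [writeReport()]
#' @exportClass TankReport
setClass("TankReport", representation(
  measurements = "data.frame",
  fishCount = "integer",
  totalBiomassKg = "numeric",
  densityKgPerM2 = "numeric",
  scaleCmPerPx = "numeric",
  sourceImageId = "character"
))

setValidity("TankReport", function(object) {
  m <- object@measurements
  need <- c("fish_id", "length_cm", "width_cm", "weight_g", "partial")
  if (!all(need %in% names(m)))
    return(paste("measurements needs columns:", paste(need, collapse = ", ")))
  if (nrow(m) > 0 && !identical(as.integer(m$fish_id), seq_len(nrow(m))))
    return("fish_id must be consecutive integers from 1")
  ok <- !m$partial & !is.na(m$weight_g)
  tot <- sum(m$weight_g[ok]) / 1000
  if (abs(tot - object@totalBiomassKg) > 1e-9 * max(1, abs(tot)))
    return("totalBiomassKg must equal the sum of non-partial weights / 1000")
  TRUE
})

#' Result of a paired t test
#'
#' @slot meanDifference mean of the paired differences (after - before).
#' @slot semDifference standard error of the mean difference.
#' @slot tStatistic t statistic.
#' @slot degreesOfFreedom n - 1.
#' @slot pValue two-sided p value.
#'
#' @seealso [pairedTtest()]
#' @exportClass PairedTestResult
setClass("PairedTestResult", representation(
  meanDifference = "numeric",
  semDifference = "numeric",
  tStatistic = "numeric",
  degreesOfFreedom = "numeric",
  pValue = "numeric"
))

#' Result of a two-sample t test
#'
#' @slot meanDifference mean(a) - mean(b).
#' @slot tStatistic t statistic.
#' @slot degreesOfFreedom Welch-Satterthwaite or pooled df.
#' @slot pValue two-sided p value.
#' @slot method "welch" or "pooled".
#'
#' @seealso [twosampleTtest()]
#' @exportClass TwoSampleTestResult
setClass("TwoSampleTestResult", representation(
  meanDifference = "numeric",
  tStatistic = "numeric",
  degreesOfFreedom = "numeric",
  pValue = "numeric",
  method = "character"
))

#' Summary of one cohort group
#'
#' Mean, standard error of the mean (sd / sqrt(n)), and the gainer
#' percentage: the share of values that are strictly positive, meaningful
#' when the input is a vector of weight increments.
#'
#' @slot n number of observations.
#' @slot mean sample mean.
#' @slot sem standard error of the mean; NA for n = 1.
#' @slot gainerPercent 100 * (positive values / n), rounded to 2 decimals.
#'
#' @seealso [summarizeGroup()]
#' @exportClass GroupSummary
setClass("GroupSummary", representation(
  n = "integer",
  mean = "numeric",
  sem = "numeric",
  gainerPercent = "numeric"
))
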