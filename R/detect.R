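# Phase 1-2: image-size normalization and scene segmentation.
#
# The default backend is classical: background level from the image median,
# Otsu thresholding of the absolute-deviation image (so both dark fish and
# the white reference are foreground), connected components, and shape
# scoring. A learned detector can be plugged in behind the same contract.

#' Construct a detector configuration
#'
#' @param resizeTargetPx target size of the shorter image side (default 1024).
#' @param minObjectAreaPx minimum component area in pixels.
#' @param contrastMethod thresholding method; currently only \code{"otsu"}.
#' @param circularityMin minimum circularity for the reference object.
#' @param elongationMin minimum elongation for a fish.
#' @param elongationMax fish blobs beyond this elongation are flagged merged.
#' @param maxFishAreaPx fish blobs beyond this area are flagged merged.
#' @param backend \code{"classical"} or \code{"plugin"}.
#' @param plugin for the plugin backend, a function \code{image -> list of}
#'   [Detection-class].
#' @return a validated [DetectorConfig-class].
#' @export
DetectorConfig <- function(resizeTargetPx = 1024L, minObjectAreaPx = 50,
                           contrastMethod = "otsu", circularityMin = 0.85,
                           elongationMin = 1.8, elongationMax = 6,
                           maxFishAreaPx = Inf, backend = "classical",
                           plugin = NULL) {
  new("DetectorConfig", resizeTargetPx = as.integer(resizeTargetPx),
      minObjectAreaPx = minObjectAreaPx, contrastMethod = contrastMethod,
      circularityMin = circularityMin, elongationMin = elongationMin,
      elongationMax = elongationMax, maxFishAreaPx = maxFishAreaPx,
      backend = backend, plugin = plugin)
}

#' Resize an image so its shorter side is exactly 1024 pixels
#'
#' The aspect ratio is preserved to within one pixel of rounding and the
#' scalar resize factor is returned so pixel counts can be mapped back to
#' the original image. Images whose shorter side already equals the target
#' are returned unchanged with factor 1; smaller images are upscaled.
#'
#' @param image numeric matrix (greyscale, values in [0, 1]).
#' @param targetPx target for the shorter side (default 1024).
#' @return list with \code{image} (resized matrix) and \code{factor}
#'   (output pixels per input pixel).
#' @examples
#' out <- resizeToPolicy(matrix(0.5, 512, 800))
#' dim(out$image)   # 1024 x 1600
#' out$factor       # 2
#' @export
resizeToPolicy <- function(image, targetPx = 1024L) {
  if (!is.matrix(image) || any(dim(image) == 0L))
    stop("image must be a non-empty 2-D matrix", call. = FALSE)
  shortSide <- min(dim(image))
  factor <- targetPx / shortSide
  if (shortSide == targetPx) return(list(image = image, factor = 1))
  newDim <- round(dim(image) * factor)
  newDim[which.min(dim(image))] <- targetPx
  resized <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                w = newDim[1], h = newDim[2]))
  list(image = clamp01(matrix(resized, newDim[1], newDim[2])),
       factor = factor)
}

# Classify one component mask; returns a Detection or NULL when the blob
# matches neither shape rule.
.classifyBlob <- function(mask, config) {
  s <- maskShapeScores(mask)
  partial <- maskTouchesBorder(mask)
  if (s$circularity >= config@circularityMin && !partial) {
    conf <- min(1, s$circularity)
    return(new("Detection", objectClass = "reference", mask = mask,
               bbox = maskBBox(mask), confidence = conf,
               circularity = s$circularity, elongation = max(1, s$elongation),
               partial = FALSE, merged = FALSE))
  }
  if (s$elongation >= config@elongationMin || partial) {
    merged <- s$elongation > config@elongationMax ||
      s$area > config@maxFishAreaPx
    conf <- clamp01(1 - exp(-(s$elongation - 1)))
    return(new("Detection", objectClass = "fish", mask = mask,
               bbox = maskBBox(mask), confidence = conf,
               circularity = s$circularity, elongation = max(1, s$elongation),
               partial = partial, merged = merged))
  }
  NULL
}

#' Segment a tank image into fish and reference detections
#'
#' Finds connected foreground components and classifies each by shape:
#' high-circularity blobs become the reference object (at most one is kept,
#' ties broken by maximum circularity then maximum area), elongated blobs
#' become fish. Blobs matching neither rule are dropped with a warning.
#' Masks touching the image border are flagged \code{partial}; fish blobs
#' exceeding the configured single-fish bounds are flagged \code{merged}.
#'
#' @param image numeric matrix, already resized per [resizeToPolicy()].
#' @param config a [DetectorConfig-class].
#' @return list of [Detection-class], sorted by bounding-box top-left
#'   corner; possibly empty. Masks are pairwise disjoint.
#' @export
segmentScene <- function(image, config = DetectorConfig()) {
  stopifnot(is(config, "DetectorConfig"))
  validObject(config)
  if (config@backend == "plugin")
    return(config@plugin(image))

  bg <- stats::median(image)
  dev <- abs(image - bg)
  thr <- EBImage::otsu(EBImage::Image(dev), range = c(0, 1), levels = 256)
  fg <- dev > thr
  # low-contrast objects lose isolated interior pixels to noise around the
  # threshold; a small closing plus hole filling restores solid blobs
  fg <- EBImage::fillHull(EBImage::closing(EBImage::Image(fg),
                                           EBImage::makeBrush(3, "disc")))
  labels <- EBImage::imageData(EBImage::bwlabel(fg))
  nLab <- max(labels)
  if (nLab == 0L) return(list())

  detections <- list()
  dropped <- 0L
  for (lab in seq_len(nLab)) {
    mask <- labels == lab
    if (sum(mask) < config@minObjectAreaPx) next
    det <- .classifyBlob(mask, config)
    if (is.null(det)) dropped <- dropped + 1L
    else detections[[length(detections) + 1L]] <- det
  }
  if (dropped > 0L)
    warning(sprintf("%d blob(s) matched neither the reference nor the fish shape rule and were dropped",
                    dropped), call. = FALSE)

  # keep a single reference: maximum circularity, then maximum area
  isRef <- vapply(detections, function(d) d@objectClass == "reference",
                  logical(1))
  if (sum(isRef) > 1L) {
    refs <- which(isRef)
    circ <- vapply(detections[refs], function(d) d@circularity, numeric(1))
    area <- vapply(detections[refs], function(d) sum(d@mask), numeric(1))
    keep <- refs[order(-circ, -area)][1L]
    demote <- setdiff(refs, keep)
    detections <- detections[-demote]
  }

  ord <- order(vapply(detections, function(d) d@bbox[1], numeric(1)),
               vapply(detections, function(d) d@bbox[2], numeric(1)))
  detections[ord]
}

#' Score detections against ground truth by greedy IoU matching
#'
#' One-to-one greedy matching per class: repeatedly pair the detection and
#' ground-truth object with the highest mask IoU at or above \code{iouMin}.
#' Accuracy is reported as per-object recall (matched / true), the
#' evaluation convention used for the detector benchmark.
#'
#' @param detections list of [Detection-class].
#' @param truth a [GroundTruth-class] in the same image coordinates.
#' @param iouMin minimum IoU for a match, in (0, 1].
#' @return data.frame with one row per class (\code{fish},
#'   \code{reference}): \code{n_true}, \code{n_detected}, \code{matched},
#'   \code{recall}, \code{precision}, \code{accuracy}.
#' @export
matchDetections <- function(detections, truth, iouMin = 0.5) {
  stopifnot(is(truth, "GroundTruth"))
  if (iouMin <= 0 || iouMin > 1)
    stop("iouMin must lie in (0, 1]", call. = FALSE)
  out <- lapply(c("fish", "reference"), function(cls) {
    dIdx <- which(vapply(detections, function(d) d@objectClass == cls,
                         logical(1)))
    tIdx <- which(vapply(truth@objects, function(o) o$class == cls,
                         logical(1)))
    nd <- length(dIdx)
    nt <- length(tIdx)
    matched <- 0L
    if (nd > 0 && nt > 0) {
      iou <- matrix(0, nd, nt)
      for (i in seq_len(nd)) for (j in seq_len(nt))
        iou[i, j] <- maskIoU(detections[[dIdx[i]]]@mask,
                             truth@objects[[tIdx[j]]]$mask)
      while (TRUE) {
        m <- which(iou == max(iou), arr.ind = TRUE)[1, , drop = FALSE]
        if (iou[m] < iouMin) break
        matched <- matched + 1L
        iou[m[1], ] <- -1
        iou[, m[2]] <- -1
        if (all(iou < iouMin)) break
      }
    }
    data.frame(class = cls, n_true = nt, n_detected = nd, matched = matched,
               recall = if (nt > 0) matched / nt else NA_real_,
               precision = if (nd > 0) matched / nd else NA_real_,
               accuracy = if (nt > 0) matched / nt else NA_real_)
  })
  do.call(rbind, out)
}
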