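# End-to-end orchestration: image in, annotated image + per-fish report out.
# Phases: resize -> segment -> calibrate -> measure -> predict -> report.

#' Construct a pipeline configuration
#'
#' @param detector a [DetectorConfig-class].
#' @param referenceDiameterCm true reference diameter (default 4.2680 cm).
#' @param tankFloorAreaM2 tank floor area in m^2; when given, the report
#'   includes the stocking density in kg/m^2.
#' @param minFishPx minimum mask pixel count for a measurable fish.
#' @return a validated [PipelineConfig-class].
#' @export
PipelineConfig <- function(detector = DetectorConfig(),
                           referenceDiameterCm = 4.2680,
                           tankFloorAreaM2 = NA_real_, minFishPx = 20) {
  new("PipelineConfig", detector = detector,
      referenceDiameterCm = referenceDiameterCm,
      tankFloorAreaM2 = tankFloorAreaM2, minFishPx = minFishPx)
}

# 3x5 bitmap digits for id overlays, row-wise from the top.
.digitFont <- lapply(list(
  `0` = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  `1` = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  `2` = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  `3` = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  `4` = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  `5` = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  `6` = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  `7` = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  `8` = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  `9` = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1)),
  function(v) matrix(v, 5, 3, byrow = TRUE))

.drawRect <- function(img, bb, value = 1, lwd = 2L) {
  r0 <- max(1L, bb[1] + 1L - lwd); r1 <- min(nrow(img), bb[3] + lwd)
  c0 <- max(1L, bb[2] + 1L - lwd); c1 <- min(ncol(img), bb[4] + lwd)
  img[r0:min(r0 + lwd - 1L, r1), c0:c1] <- value
  img[max(r0, r1 - lwd + 1L):r1, c0:c1] <- value
  img[r0:r1, c0:min(c0 + lwd - 1L, c1)] <- value
  img[r0:r1, max(c0, c1 - lwd + 1L):c1] <- value
  img
}

.drawNumber <- function(img, number, row, col, value = 1, scale = 3L) {
  digits <- strsplit(as.character(number), "")[[1]]
  for (d in digits) {
    glyph <- .digitFont[[d]]
    if (is.null(glyph)) next
    big <- glyph[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
    rr <- row:(row + nrow(big) - 1L)
    cc <- col:(col + ncol(big) - 1L)
    ok <- rr <= nrow(img) & rr >= 1L
    okc <- cc <= ncol(img) & cc >= 1L
    sub <- img[rr[ok], cc[okc], drop = FALSE]
    sub[big[ok, okc, drop = FALSE] == 1] <- value
    img[rr[ok], cc[okc]] <- sub
    col <- col + (3L + 1L) * scale
  }
  img
}

.drawCircleOutline <- function(img, bb, value = 1) {
  cr <- (bb[1] + bb[3]) / 2
  cc <- (bb[2] + bb[4]) / 2
  rad <- (bb[3] - bb[1] + bb[4] - bb[2]) / 4
  th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rad) * 2)
  for (w in c(rad + 2, rad + 3)) {
    rr <- pmin(nrow(img), pmax(1, round(cr + w * sin(th))))
    ccol <- pmin(ncol(img), pmax(1, round(cc + w * cos(th))))
    img[cbind(rr, ccol)] <- value
  }
  img
}

#' Run the full biomass-estimation pipeline on one tank image
#'
#' Normalizes the image size, segments fish and the reference object,
#' self-calibrates the metric scale from the reference, measures every
#' non-partial, non-merged fish with the minimum-area rotated rectangle,
#' predicts each individual weight with the supplied regressor, and
#' assembles a [TankReport-class] plus an annotated copy of the image (fish
#' bounding boxes with their id numbers and the reference circled).
#'
#' Fish are numbered 1..n by bounding-box top-left corner (row, then
#' column), so ids are deterministic for a given image. Partial or merged
#' fish appear in the report with \code{NA} measurements and
#' \code{partial = TRUE}; they are excluded from the totals.
#'
#' @param image numeric greyscale matrix in [0, 1], or a path readable by
#'   [readGreyImage()].
#' @param config a [PipelineConfig-class].
#' @param model a trained [BiomassModel-class].
#' @param imageId identifier recorded in the report; defaults to the file
#'   name when \code{image} is a path.
#' @return list with \code{annotated} (numeric matrix) and \code{report}
#'   (a [TankReport-class]).
#' @section Errors: if no usable reference object is found the pipeline
#'   aborts with a typed \code{calibrationError}. A scene without fish
#'   yields a valid empty report with a warning.
#' @export
runPipeline <- function(image, config = PipelineConfig(), model,
                        imageId = NULL) {
  stopifnot(is(config, "PipelineConfig"), is(model, "BiomassModel"))
  validObject(config)
  if (is.character(image)) {
    if (is.null(imageId)) imageId <- basename(image)
    image <- readGreyImage(image)
  }
  if (is.null(imageId)) imageId <- "image"

  rs <- resizeToPolicy(image, config@detector@resizeTargetPx)
  dets <- segmentScene(rs$image, config@detector)

  refs <- Filter(function(d) d@objectClass == "reference", dets)
  if (length(refs) == 0L)
    calibrationError("no reference object found in the image; the pipeline cannot self-calibrate. Place the reference hemisphere in the tank and retake the photo")
  cal <- calibrateFromReference(refs[[1]], config@referenceDiameterCm)

  fish <- Filter(function(d) d@objectClass == "fish", dets)
  if (length(fish) == 0L)
    warning("no fish detected; returning an empty report", call. = FALSE)

  rows <- lapply(seq_along(fish), function(i) {
    d <- fish[[i]]
    m <- tryCatch(measureFish(d, cal, objectId = i,
                              minPixels = config@minFishPx),
                  measurementSkipped = function(e) NULL,
                  degenerateMask = function(e) NULL)
    if (is.null(m))
      data.frame(fish_id = i, length_cm = NA_real_, width_cm = NA_real_,
                 weight_g = NA_real_, partial = TRUE)
    else
      data.frame(fish_id = i, length_cm = m@lengthCm, width_cm = m@widthCm,
                 weight_g = predictWeight(model, m@lengthCm, m@widthCm,
                                          warn = FALSE),
                 partial = FALSE)
  })
  meas <- if (length(rows)) do.call(rbind, rows)
          else data.frame(fish_id = integer(), length_cm = numeric(),
                          width_cm = numeric(), weight_g = numeric(),
                          partial = logical())

  ok <- !meas$partial
  total <- sum(meas$weight_g[ok]) / 1000
  density <- if (is.na(config@tankFloorAreaM2)) NA_real_
             else total / config@tankFloorAreaM2
  report <- new("TankReport", measurements = meas,
                fishCount = sum(ok), totalBiomassKg = total,
                densityKgPerM2 = density, scaleCmPerPx = cal@scaleCmPerPx,
                sourceImageId = imageId)

  annotated <- rs$image
  annotated <- .drawCircleOutline(annotated, refs[[1]]@bbox, value = 0)
  for (i in seq_along(fish)) {
    bb <- fish[[i]]@bbox
    annotated <- .drawRect(annotated, bb, value = 1)
    annotated <- .drawNumber(annotated, i, max(1L, bb[1] - 18L),
                             bb[2] + 2L, value = 1)
  }
  list(annotated = annotated, report = report)
}

#' Write and read a tank report
#'
#' The per-fish table goes to CSV with header
#' \code{fish_id,length_cm,width_cm,weight_g,partial}; the totals (fish
#' count, total biomass, density, calibration scale, source image, and the
#' daily feed ration \code{ration_kg = 0.005 * total_biomass_kg}) go to a
#' side-car JSON named \code{<path-without-ext>_totals.json}. Numbers are
#' written at full double precision, so \code{readReport} reproduces the
#' report exactly and repeated writes are byte-identical.
#'
#' @param report a [TankReport-class].
#' @param path CSV file path.
#' @return \code{readReport} returns the [TankReport-class]; the writer
#'   returns \code{path} invisibly.
#' @name reportIO
NULL

.totalsPath <- function(path)
  paste0(sub("\\.[Cc][Ss][Vv]$", "", path), "_totals.json")

#' @rdname reportIO
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "TankReport"))
  validObject(report)
  m <- report@measurements
  out <- data.frame(fish_id = m$fish_id,
                    length_cm = sprintf("%.17g", m$length_cm),
                    width_cm = sprintf("%.17g", m$width_cm),
                    weight_g = sprintf("%.17g", m$weight_g),
                    partial = m$partial)
  if (nrow(out)) out[m$partial, c("length_cm", "width_cm", "weight_g")] <- "NA"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fish_count = report@fishCount,
         total_biomass_kg = report@totalBiomassKg,
         density_kg_per_m2 = report@densityKgPerM2,
         scale_cm_per_px = report@scaleCmPerPx,
         source_image_id = report@sourceImageId,
         ration_kg = 0.005 * report@totalBiomassKg),
    .totalsPath(path), auto_unbox = TRUE, digits = I(17), na = "null",
    pretty = TRUE)
  invisible(path)
}

#' @rdname reportIO
#' @export
readReport <- function(path) {
  m <- utils::read.csv(path, colClasses = c(fish_id = "integer",
                                            length_cm = "numeric",
                                            width_cm = "numeric",
                                            weight_g = "numeric",
                                            partial = "logical"))
  tot <- jsonlite::read_json(.totalsPath(path), simplifyVector = TRUE)
  new("TankReport", measurements = m,
      fishCount = as.integer(tot$fish_count),
      totalBiomassKg = as.numeric(tot$total_biomass_kg),
      densityKgPerM2 = if (is.null(tot$density_kg_per_m2)) NA_real_
                       else as.numeric(tot$density_kg_per_m2),
      scaleCmPerPx = as.numeric(tot$scale_cm_per_px),
      sourceImageId = as.character(tot$source_image_id))
}
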