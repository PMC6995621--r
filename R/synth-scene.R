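# Synthetic top-view tank scenes with exact ground truth.
#
# The renderer stands in for the unavailable tank photographs: grey tank
# floor, sole-shaped dark silhouettes, and one white circle of known metric
# diameter. Masks are recorded before pixel noise is applied, so every
# downstream phase (detection, calibration, morphometry, biomass) can be
# scored against exact annotations.

# Default allometric relationship used for ground-truth fish weights:
# W = alpha * L^2 * W_b, with alpha calibrated so a 35 cm x 14 cm sole
# weighs 750 g (adult animals around 0.75 kg).
.allomAlpha <- 750 / (35^2 * 14)
.allomBeta <- 2
.allomGamma <- 1

#' Default allometric weight of a sole from its body dimensions
#'
#' Power-law length-weight relationship \eqn{W = \alpha L^{\beta} w^{\gamma}}
#' with \eqn{\beta = 2}, \eqn{\gamma = 1} and \eqn{\alpha} calibrated so a
#' 35 cm x 14 cm fish weighs 750 g. This is the relationship the synthetic
#' generators use for ground-truth weights.
#'
#' @param lengthCm body length in cm.
#' @param widthCm body width in cm.
#' @return weight in grams.
#' @examples
#' defaultAllometricWeight(35, 14)  # 750
#' @export
defaultAllometricWeight <- function(lengthCm, widthCm) {
  .allomAlpha * lengthCm^.allomBeta * widthCm^.allomGamma
}

#' Describe one synthetic fish silhouette
#'
#' Returns a validated one-row data.frame in the schema of the \code{fish}
#' slot of [SceneSpec-class]. The silhouette is an ellipse of the given
#' length and width whose tail half is narrowed by the \code{taper}
#' coefficient (0 = pure ellipse, 1 = fully tapered tail); its maximum width
#' and total length remain exactly \code{widthCm} and \code{lengthCm}.
#'
#' @param lengthCm body length (major axis) in cm; must exceed widthCm.
#' @param widthCm body width (minor axis) in cm.
#' @param row,col centroid position in continuous pixel coordinates.
#' @param orientationDeg major-axis angle in degrees, reduced to [0, 180).
#' @param intensity mean grey level of the fish in [0, 1].
#' @param taper tail taper coefficient in [0, 1].
#' @return one-row data.frame with the fish-spec columns.
#' @export
FishSpec <- function(lengthCm, widthCm, row, col, orientationDeg = 0,
                     intensity = 0.22, taper = 0.4) {
  if (lengthCm <= widthCm || widthCm <= 0)
    stop("need lengthCm > widthCm > 0", call. = FALSE)
  if (taper < 0 || taper > 1) stop("taper must lie in [0, 1]", call. = FALSE)
  data.frame(length_cm = lengthCm, width_cm = widthCm, row = row, col = col,
             orientation_deg = orientationDeg %% 180, intensity = intensity,
             taper = taper)
}

#' Construct a synthetic scene specification
#'
#' @param imageShape integer(2), image size (rows, cols) in pixels.
#' @param fish data.frame of fish rows from [FishSpec()] (rbind them), or an
#'   empty data.frame for a fish-free scene.
#' @param scaleTrue true metric scale in cm per pixel.
#' @param referenceCenter numeric(2), reference-circle centre (row, col).
#' @param referenceDiameterCm true reference diameter in cm.
#' @param referenceIntensity grey level of the white reference object.
#' @param backgroundIntensity mean grey level of the tank floor.
#' @param backgroundNoiseSd sd of additive Gaussian pixel noise.
#' @param allowOverlap allow object masks to overlap (default FALSE).
#' @param seed RNG seed for the pixel noise.
#' @return a validated [SceneSpec-class].
#' @seealso [randomSceneSpec()] for randomly populated scenes.
#' @export
SceneSpec <- function(imageShape = c(1024L, 1024L), fish = emptyFishTable(),
                      scaleTrue = 0.1, referenceCenter = NULL,
                      referenceDiameterCm = 4.2680, referenceIntensity = 0.95,
                      backgroundIntensity = 0.45, backgroundNoiseSd = 0.02,
                      allowOverlap = FALSE, seed = 1L) {
  if (is.null(referenceCenter))
    referenceCenter <- imageShape / 2
  new("SceneSpec", imageShape = as.integer(imageShape),
      backgroundIntensity = backgroundIntensity,
      backgroundNoiseSd = backgroundNoiseSd, scaleTrue = scaleTrue,
      referenceDiameterCm = referenceDiameterCm,
      referenceCenter = as.numeric(referenceCenter),
      referenceIntensity = referenceIntensity,
      fish = fish, allowOverlap = allowOverlap, seed = as.integer(seed))
}

#' @rdname SceneSpec
#' @export
emptyFishTable <- function() {
  data.frame(length_cm = numeric(), width_cm = numeric(), row = numeric(),
             col = numeric(), orientation_deg = numeric(),
             intensity = numeric(), taper = numeric())
}

# Analytic half-extents (rows, cols) of a rotated ellipse-like silhouette.
silhouetteHalfExtent <- function(majorPx, minorPx, angleDeg) {
  th <- angleDeg * pi / 180
  a <- majorPx / 2
  b <- minorPx / 2
  c(row = sqrt((a * sin(th))^2 + (b * cos(th))^2),
    col = sqrt((a * cos(th))^2 + (b * sin(th))^2))
}

# Full-frame logical mask of a tapered-ellipse silhouette. The local
# half-width at normalized axial position u in [-1, 1] is
# (minor/2) * sqrt(1 - u^2) for the head half (u <= 0) and additionally
# scaled by (1 - taper * u^2) on the tail half, so maximum width and total
# length are exact.
silhouetteMask <- function(rows, cols, centerRow, centerCol, majorPx, minorPx,
                           angleDeg, taper = 0) {
  he <- silhouetteHalfExtent(majorPx, minorPx, angleDeg)
  r1 <- max(1L, floor(centerRow - he["row"]))
  r2 <- min(rows, ceiling(centerRow + he["row"] + 1))
  c1 <- max(1L, floor(centerCol - he["col"]))
  c2 <- min(cols, ceiling(centerCol + he["col"] + 1))
  mask <- matrix(FALSE, rows, cols)
  if (r1 > r2 || c1 > c2) return(mask)
  th <- angleDeg * pi / 180
  rr <- seq(r1, r2)
  cc <- seq(c1, c2)
  y <- (rr - 0.5) - centerRow
  x <- (cc - 0.5) - centerCol
  X <- matrix(x, nrow = length(rr), ncol = length(cc), byrow = TRUE)
  Y <- matrix(y, nrow = length(rr), ncol = length(cc))
  dx <- X * cos(th) + Y * sin(th)     # along major axis
  dy <- -X * sin(th) + Y * cos(th)    # along minor axis
  u <- dx / (majorPx / 2)
  halfw <- (minorPx / 2) * sqrt(pmax(0, 1 - u^2))
  tailScale <- ifelse(u > 0, 1 - taper * u^2, 1)
  inside <- abs(u) < 1 & abs(dy) <= halfw * tailScale
  mask[rr, cc] <- inside
  mask
}

circleMask <- function(rows, cols, centerRow, centerCol, diameterPx) {
  rad <- diameterPx / 2
  r1 <- max(1L, floor(centerRow - rad))
  r2 <- min(rows, ceiling(centerRow + rad + 1))
  c1 <- max(1L, floor(centerCol - rad))
  c2 <- min(cols, ceiling(centerCol + rad + 1))
  mask <- matrix(FALSE, rows, cols)
  if (r1 > r2 || c1 > c2) return(mask)
  rr <- seq(r1, r2)
  cc <- seq(c1, c2)
  y <- (rr - 0.5) - centerRow
  x <- (cc - 0.5) - centerCol
  X <- matrix(x, nrow = length(rr), ncol = length(cc), byrow = TRUE)
  Y <- matrix(y, nrow = length(rr), ncol = length(cc))
  mask[rr, cc] <- X^2 + Y^2 <= rad^2
  mask
}

#' Render a synthetic scene to an image and its ground truth
#'
#' Draws every fish as a tapered-ellipse silhouette and the reference object
#' as a filled circle of diameter \code{referenceDiameterCm / scaleTrue}
#' pixels, records the exact masks, then adds Gaussian pixel noise. The
#' result is a pure function of the spec (including its seed).
#'
#' @param spec a [SceneSpec-class].
#' @return list with \code{image} (numeric matrix in [0, 1]) and
#'   \code{truth} (a [GroundTruth-class]; the reference object is last).
#' @section Errors: objects extending beyond the image frame are rejected,
#'   as are overlapping masks when \code{allowOverlap} is FALSE.
#' @examples
#' sc <- renderScene(SceneSpec(imageShape = c(256L, 256L), scaleTrue = 0.05,
#'                             seed = 1L))
#' sc$truth
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  rows <- spec@imageShape[1]
  cols <- spec@imageShape[2]
  refDiamPx <- spec@referenceDiameterCm / spec@scaleTrue

  # frame checks on analytic extents (continuous coords in [0, rows] x [0, cols])
  rc <- spec@referenceCenter
  if (rc[1] - refDiamPx / 2 < 0 || rc[1] + refDiamPx / 2 > rows ||
      rc[2] - refDiamPx / 2 < 0 || rc[2] + refDiamPx / 2 > cols)
    stop("reference object extends beyond the image frame", call. = FALSE)

  objects <- list()
  occupancy <- matrix(FALSE, rows, cols)
  img <- matrix(spec@backgroundIntensity, rows, cols)

  f <- spec@fish
  if (nrow(f) > 0) {
    for (i in seq_len(nrow(f))) {
      majorPx <- f$length_cm[i] / spec@scaleTrue
      minorPx <- f$width_cm[i] / spec@scaleTrue
      he <- silhouetteHalfExtent(majorPx, minorPx, f$orientation_deg[i])
      if (f$row[i] - he["row"] < 0 || f$row[i] + he["row"] > rows ||
          f$col[i] - he["col"] < 0 || f$col[i] + he["col"] > cols)
        stop(sprintf("fish %d extends beyond the image frame", i),
             call. = FALSE)
      mask <- silhouetteMask(rows, cols, f$row[i], f$col[i], majorPx, minorPx,
                             f$orientation_deg[i], f$taper[i])
      if (!spec@allowOverlap && any(mask & occupancy))
        stop(sprintf("fish %d overlaps a previously placed object", i),
             call. = FALSE)
      occupancy <- occupancy | mask
      img[mask] <- f$intensity[i]
      objects[[length(objects) + 1L]] <- list(
        class = "fish", mask = mask, bbox = maskBBox(mask),
        length_cm = f$length_cm[i], width_cm = f$width_cm[i],
        weight_g = defaultAllometricWeight(f$length_cm[i], f$width_cm[i]))
    }
  }

  refMask <- circleMask(rows, cols, rc[1], rc[2], refDiamPx)
  if (!spec@allowOverlap && any(refMask & occupancy))
    stop("reference object overlaps a fish", call. = FALSE)
  img[refMask] <- spec@referenceIntensity
  objects[[length(objects) + 1L]] <- list(
    class = "reference", mask = refMask, bbox = maskBBox(refMask),
    length_cm = spec@referenceDiameterCm, width_cm = spec@referenceDiameterCm,
    weight_g = NA_real_)

  if (spec@backgroundNoiseSd > 0) {
    img <- withSeed(spec@seed, {
      clamp01(img + matrix(stats::rnorm(rows * cols, 0,
                                        spec@backgroundNoiseSd), rows, cols))
    })
  }

  list(image = img,
       truth = new("GroundTruth", objects = objects,
                   scaleTrue = spec@scaleTrue))
}

#' Randomly populate a scene with non-overlapping fish
#'
#' Samples fish dimensions, positions and orientations under the default
#' study conditions (grey tank, 20-40 cm soles, one white reference circle)
#' and places them by rejection so that all silhouettes, enlarged by a small
#' safety margin, are pairwise disjoint and clear of the image border.
#'
#' @param nFish number of fish to place.
#' @param seed RNG seed driving both placement and pixel noise.
#' @param imageShape image size in pixels (rows, cols).
#' @param scaleTrue true metric scale in cm per pixel.
#' @param lengthRangeCm uniform sampling range of body length.
#' @param aspectRange uniform range of the width/length ratio.
#' @param intensityRange uniform range of fish grey level.
#' @param taperRange uniform range of the tail-taper coefficient.
#' @param marginPx minimum clearance between objects and to the border.
#' @param ... further arguments passed to [SceneSpec()].
#' @return a [SceneSpec-class].
#' @export
randomSceneSpec <- function(nFish = 5, seed = 1L,
                            imageShape = c(1024L, 1024L), scaleTrue = 0.1,
                            lengthRangeCm = c(20, 40),
                            aspectRange = c(0.30, 0.50),
                            intensityRange = c(0.15, 0.30),
                            taperRange = c(0.2, 0.6),
                            marginPx = 6, ...) {
  rows <- imageShape[1]
  cols <- imageShape[2]
  withSeed(seed, {
    occupancy <- matrix(FALSE, rows, cols)
    refDiamPx <- 4.2680 / scaleTrue
    place <- function(majorPx, minorPx, angle, taper) {
      he <- silhouetteHalfExtent(majorPx + 2 * marginPx, minorPx + 2 * marginPx,
                                 angle)
      for (try in seq_len(500)) {
        r <- stats::runif(1, he["row"] + 1, rows - he["row"] - 1)
        c <- stats::runif(1, he["col"] + 1, cols - he["col"] - 1)
        m <- silhouetteMask(rows, cols, r, c, majorPx + 2 * marginPx,
                            minorPx + 2 * marginPx, angle, taper)
        if (!any(m & occupancy)) {
          occupancy <<- occupancy | m
          return(c(r, c))
        }
      }
      stop("could not place all objects without overlap; reduce nFish",
           call. = FALSE)
    }
    refPos <- place(refDiamPx, refDiamPx * 0.999, 0, 0)
    fish <- emptyFishTable()
    for (i in seq_len(nFish)) {
      len <- stats::runif(1, lengthRangeCm[1], lengthRangeCm[2])
      wid <- len * stats::runif(1, aspectRange[1], aspectRange[2])
      ang <- stats::runif(1, 0, 180)
      tap <- stats::runif(1, taperRange[1], taperRange[2])
      inten <- stats::runif(1, intensityRange[1], intensityRange[2])
      pos <- place(len / scaleTrue, wid / scaleTrue, ang, tap)
      fish <- rbind(fish, FishSpec(len, wid, pos[1], pos[2], ang, inten, tap))
    }
    SceneSpec(imageShape = as.integer(imageShape), fish = fish,
              scaleTrue = scaleTrue, referenceCenter = refPos,
              seed = seed, ...)
  })
}
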