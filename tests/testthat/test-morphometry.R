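fishDetection <- function(mask, partial = FALSE, merged = FALSE) {
  new("Detection", objectClass = "fish", mask = mask,
      bbox = soleVision:::maskBBox(mask), confidence = 1, circularity = 0.5,
      elongation = 2, partial = partial, merged = merged)
}

calAt <- function(scale) {
  d <- 4.2680 / scale
  m <- soleVision:::circleMask(ceiling(d) + 20, ceiling(d) + 20,
                               (ceiling(d) + 20) / 2, (ceiling(d) + 20) / 2, d)
  new("CalibrationResult", scaleCmPerPx = 4.2680 / (2 * sqrt(sum(m) / pi)),
      referenceDiameterPx = 2 * sqrt(sum(m) / pi), bboxDiameterPx = d,
      circularity = 1, referenceDiameterCm = 4.2680)
}

test_that("an axis-aligned ellipse measures to its drawn dimensions", {
  mask <- soleVision:::silhouetteMask(300, 300, 150, 150, 200, 60, 0, 0)
  cal <- calAt(0.05)
  m <- measureFish(fishDetection(mask), cal)
  expect_equal(m@lengthCm, 10, tolerance = 2 * 0.05 / 10)
  expect_equal(m@widthCm, 3, tolerance = 2 * 0.05 / 3)
})

test_that("measurements are rotation invariant within the discretization bound", {
  cal <- calAt(0.05)
  angles <- seq(0, 165, by = 15)
  lengths <- numeric(0)
  widths <- numeric(0)
  for (ang in angles) {
    mask <- soleVision:::silhouetteMask(400, 400, 200, 200, 200, 60, ang, 0.4)
    m <- measureFish(fishDetection(mask), cal)
    lengths <- c(lengths, m@lengthCm)
    widths <- c(widths, m@widthCm)
    # independent oracle: extents along the PCA axes of the analytic mask
    pts <- soleVision:::maskPoints(mask)
    ctr <- colMeans(pts)
    ev <- eigen(stats::cov(pts))$vectors
    proj <- sweep(pts, 2, ctr) %*% ev
    oracleLen <- (max(proj[, 1]) - min(proj[, 1]) + 1) * 0.05
    expect_equal(m@lengthCm, oracleLen, tolerance = 0.02)
  }
  expect_lt(diff(range(lengths)), 2 * 0.05 * 2)
  expect_lt(diff(range(widths)), 2 * 0.05 * 2)
})

test_that("partial, merged and degenerate masks raise typed conditions", {
  cal <- calAt(0.05)
  mask <- soleVision:::silhouetteMask(300, 300, 150, 150, 200, 60, 0, 0)
  expect_error(measureFish(fishDetection(mask, partial = TRUE), cal),
               class = "measurementSkipped")
  expect_error(measureFish(fishDetection(mask, merged = TRUE), cal),
               class = "measurementSkipped")
  tiny <- matrix(FALSE, 50, 50)
  tiny[25, 25] <- TRUE
  expect_error(measureFish(fishDetection(tiny), cal),
               class = "degenerateMask")
})

test_that("median relative measurement error stays small on random scenes", {
  errL <- c()
  errW <- c()
  for (s in 201:204) {
    spec <- randomSceneSpec(nFish = 5, seed = s)
    sc <- renderScene(spec)
    dets <- segmentScene(sc$image)
    cal <- calibrateFromReference(
      Filter(function(d) objectClass(d) == "reference", dets)[[1]])
    truthFish <- Filter(function(o) o$class == "fish", sc$truth@objects)
    for (f in Filter(function(d) objectClass(d) == "fish", dets)) {
      m <- measureFish(f, cal)
      ious <- vapply(truthFish, function(o)
        soleVision:::maskIoU(maskOf(f), o$mask), numeric(1))
      tr <- truthFish[[which.max(ious)]]
      errL <- c(errL, abs(m@lengthCm - tr$length_cm) / tr$length_cm)
      errW <- c(errW, abs(m@widthCm - tr$width_cm) / tr$width_cm)
    }
  }
  expect_lt(stats::median(errL), 0.005)
  expect_lt(stats::median(errW), 0.004)
})
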