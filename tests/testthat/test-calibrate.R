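makeDetection <- function(mask, cls = "reference") {
  new("Detection", objectClass = cls, mask = mask,
      bbox = soleVision:::maskBBox(mask), confidence = 1,
      circularity = soleVision:::maskShapeScores(mask)$circularity,
      elongation = 1, partial = FALSE, merged = FALSE)
}

test_that("the scale is the known diameter over the equivalent-area pixel diameter", {
  m <- soleVision:::circleMask(300, 300, 150, 150, 100)
  cal <- calibrateFromReference(makeDetection(m))
  dPx <- 2 * sqrt(sum(m) / pi)
  expect_identical(scaleCmPerPx(cal), 4.2680 / dPx)
  expect_equal(dPx, 100, tolerance = 0.01)
  expect_equal(scaleCmPerPx(cal), 0.042680, tolerance = 1e-3)
  # conservation identity enforced by the class
  expect_equal(scaleCmPerPx(cal) * cal@referenceDiameterPx, 4.2680)
})

test_that("the true scene scale is recovered within 1%", {
  sc <- renderScene(referenceOnlyScene(scaleTrue = 0.05))
  dets <- segmentScene(sc$image)
  cal <- calibrateFromReference(dets[[1]])
  expect_equal(scaleCmPerPx(cal), 0.05, tolerance = 0.01)
})

test_that("a non-circular mask fails calibration with a typed error", {
  elongated <- soleVision:::silhouetteMask(300, 300, 150, 150, 150, 50, 30, 0)
  expect_error(calibrateFromReference(makeDetection(elongated)),
               class = "calibrationError")
  fish <- makeDetection(soleVision:::circleMask(100, 100, 50, 50, 40), "fish")
  expect_error(calibrateFromReference(fish), "not a reference")
})

test_that("halving the resolution doubles the scale while conserving scale x diameter", {
  calAt <- function(scaleTrue) {
    sc <- renderScene(referenceOnlyScene(scaleTrue = scaleTrue,
                                         shape = c(512L, 512L)))
    calibrateFromReference(segmentScene(sc$image)[[1]])
  }
  fine <- calAt(0.04)
  coarse <- calAt(0.08)
  expect_equal(scaleCmPerPx(coarse) / scaleCmPerPx(fine), 2, tolerance = 0.01)
  expect_equal(scaleCmPerPx(fine) * fine@referenceDiameterPx, 4.2680)
  expect_equal(scaleCmPerPx(coarse) * coarse@referenceDiameterPx, 4.2680)
})

test_that("phase-averaged scale error shrinks monotonically with reference size in pixels", {
  set.seed(42)
  meanErr <- vapply(c(20, 50, 100, 200), function(D) {
    mean(replicate(40, {
      m <- soleVision:::circleMask(300, 300, 150 + stats::runif(1),
                                   150 + stats::runif(1), D)
      abs(2 * sqrt(sum(m) / pi) - D) / D
    }))
  }, numeric(1))
  expect_true(all(diff(meanErr) < 0))
})
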