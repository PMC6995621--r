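test_that("the resize policy brings the shorter side to exactly 1024 px, preserving aspect", {
  big <- resizeToPolicy(matrix(0.5, 2048, 1536))
  expect_identical(dim(big$image), c(1365L, 1024L))
  expect_equal(big$factor, 1024 / 1536)

  same <- resizeToPolicy(matrix(0.5, 1024, 1024))
  expect_identical(dim(same$image), c(1024L, 1024L))
  expect_identical(same$factor, 1)

  small <- resizeToPolicy(matrix(0.5, 512, 800))
  expect_identical(dim(small$image), c(1024L, 1600L))
  expect_equal(small$factor, 2)

  expect_error(resizeToPolicy(matrix(numeric(), 0, 0)), "non-empty")
})

test_that("segmentation recovers all rendered objects with high mask fidelity", {
  s <- segmentedRandomScene(seed = 3)
  expect_length(s$fish, 5L)
  expect_length(s$reference, 1L)
  truthObjs <- s$scene$truth@objects
  for (d in c(s$fish, s$reference)) {
    ious <- vapply(truthObjs, function(o) soleVision:::maskIoU(maskOf(d),
                                                               o$mask),
                   numeric(1))
    expect_gte(max(ious), 0.95)
  }
})

test_that("degenerate scenes segment sensibly", {
  blank <- matrix(0.45, 512, 512)
  expect_identical(segmentScene(blank), list())

  refOnly <- renderScene(referenceOnlyScene())
  dets <- segmentScene(refOnly$image)
  expect_length(dets, 1L)
  expect_identical(objectClass(dets[[1]]), "reference")
})

test_that("detections are deterministic and pairwise disjoint", {
  sc <- renderScene(randomSceneSpec(nFish = 4, seed = 8))
  a <- segmentScene(sc$image)
  b <- segmentScene(sc$image)
  expect_identical(lapply(a, maskOf), lapply(b, maskOf))
  overlap <- Reduce(`+`, lapply(a, function(d) maskOf(d) * 1L))
  expect_lte(max(overlap), 1L)
})

test_that("classification is equivariant to rendering the same scene at double resolution", {
  fish <- rbind(FishSpec(20, 7, 150, 150, 25, taper = 0.5),
                FishSpec(30, 13, 320, 330, 120, taper = 0.3))
  lo <- SceneSpec(imageShape = c(512L, 512L), fish = fish, scaleTrue = 0.2,
                  referenceCenter = c(120, 350), seed = 2)
  fishHi <- fish
  fishHi$row <- fish$row * 2
  fishHi$col <- fish$col * 2
  hi <- SceneSpec(imageShape = c(1024L, 1024L), fish = fishHi,
                  scaleTrue = 0.1, referenceCenter = c(240, 700), seed = 2)
  clsOf <- function(spec) {
    dets <- segmentScene(renderScene(spec)$image)
    sort(vapply(dets, objectClass, character(1)))
  }
  expect_identical(clsOf(lo), clsOf(hi))
  expect_identical(clsOf(hi), c("fish", "fish", "reference"))
})

test_that("fish clipped by the image border are detected but flagged partial", {
  img <- matrix(0.45, 512, 512)
  mask <- soleVision:::silhouetteMask(512, 512, 4, 250, 220, 80, 10, 0.4)
  img[mask] <- 0.2
  img[soleVision:::circleMask(512, 512, 400, 400, 42.7)] <- 0.95
  dets <- segmentScene(img)
  cls <- vapply(dets, objectClass, character(1))
  expect_setequal(cls, c("fish", "reference"))
  fish <- dets[[which(cls == "fish")]]
  expect_true(fish@partial)
})

test_that("greedy IoU matching reports per-class recall as accuracy", {
  sc <- renderScene(randomSceneSpec(nFish = 5, seed = 13))
  truthAsDets <- lapply(sc$truth@objects, function(o)
    new("Detection", objectClass = o$class, mask = o$mask, bbox = o$bbox,
        confidence = 1, circularity = 1, elongation = 1, partial = FALSE,
        merged = FALSE))
  perfect <- matchDetections(truthAsDets, sc$truth)
  expect_equal(perfect$accuracy, c(1, 1))
  expect_equal(perfect$precision, c(1, 1))

  none <- matchDetections(list(), sc$truth)
  expect_equal(none$accuracy[none$class == "fish"], 0)

  expect_error(matchDetections(list(), sc$truth, iouMin = 0), "iouMin")
  expect_error(matchDetections(list(), sc$truth, iouMin = 1.5), "iouMin")
})
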