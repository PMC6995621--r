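test_that("a fish-free scene renders exactly one reference circle of the expected diameter", {
  sc <- renderScene(referenceOnlyScene(scaleTrue = 0.05))
  objs <- sc$truth@objects
  expect_length(objs, 1L)
  expect_identical(objs[[1]]$class, "reference")
  # 4.2680 cm / 0.05 cm/px = 85.36 px equivalent-area diameter
  expect_equal(2 * sqrt(sum(objs[[1]]$mask) / pi), 85.36, tolerance = 0.01)
  bb <- objs[[1]]$bbox
  expect_identical(bb, soleVision:::maskBBox(objs[[1]]$mask))
})

test_that("a populated scene yields one object per fish plus the reference, with disjoint masks", {
  sc <- renderScene(randomSceneSpec(nFish = 5, seed = 11))
  objs <- sc$truth@objects
  expect_length(objs, 6L)
  expect_identical(sum(vapply(objs, function(o) o$class == "fish",
                              logical(1))), 5L)
  overlap <- Reduce(`+`, lapply(objs, function(o) o$mask * 1L))
  expect_lte(max(overlap), 1L)
  # bboxes are tight around the recorded masks
  for (o in objs) expect_identical(o$bbox, soleVision:::maskBBox(o$mask))
})

test_that("rendering is a pure function of the spec: same seed gives bit-identical images", {
  spec <- randomSceneSpec(nFish = 3, seed = 21)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(a$image, b$image)
  c <- renderScene(randomSceneSpec(nFish = 3, seed = 22))
  expect_false(identical(a$image, c$image))
})

test_that("out-of-frame and overlapping objects are rejected with explicit messages", {
  offFrame <- SceneSpec(imageShape = c(256L, 256L), scaleTrue = 0.1,
                        fish = FishSpec(20, 8, row = 5, col = 128))
  expect_error(renderScene(offFrame), "beyond the image frame")
  twoOnTop <- SceneSpec(imageShape = c(512L, 512L), scaleTrue = 0.1,
                        referenceCenter = c(450, 450),
                        fish = rbind(FishSpec(20, 8, 200, 200, 30),
                                     FishSpec(22, 9, 210, 205, 60)))
  expect_error(renderScene(twoOnTop), "overlap")
  expect_silent(renderScene(SceneSpec(imageShape = c(512L, 512L),
                                      scaleTrue = 0.1,
                                      referenceCenter = c(450, 450),
                                      fish = rbind(FishSpec(20, 8, 200, 200, 30),
                                                   FishSpec(22, 9, 210, 205, 60)),
                                      allowOverlap = TRUE)))
})

test_that("measuring a recorded mask reproduces the spec dimensions within the discretization bound", {
  spec <- randomSceneSpec(nFish = 4, seed = 31)
  sc <- renderScene(spec)
  scale <- spec@scaleTrue
  fishObjs <- Filter(function(o) o$class == "fish", sc$truth@objects)
  for (o in fishObjs) {
    r <- soleVision:::minAreaRect(soleVision:::maskPoints(o$mask))
    expect_lt(abs((r$major + 1) * scale - o$length_cm), 2 * scale)
    expect_lt(abs((r$minor + 1) * scale - o$width_cm), 2 * scale)
  }
})

test_that("biomass dataset generation follows the power law and rejects bad inputs", {
  expect_error(generateBiomassDataset(n = 1), "at least")
  expect_error(generateBiomassDataset(alpha = 0), "alpha")
  d <- generateBiomassDataset(n = 2, alpha = 0.01, beta = 2, gamma = 1,
                              noiseCv = 0, seed = 1,
                              lengths = c(10, 20), widths = c(4, 8))
  expect_equal(d$weight_g, c(4, 32))
  # determinism
  a <- generateBiomassDataset(n = 50, seed = 9)
  b <- generateBiomassDataset(n = 50, seed = 9)
  expect_identical(a, b)
  # noise-free data lies exactly on the power-law surface
  nf <- generateBiomassDataset(n = 100, noiseCv = 0, seed = 2)
  fit <- stats::lm(log(weight_g) ~ log(length_cm) + log(width_cm), data = nf)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
})

test_that("growth cohort generation respects group geometry and the identity case", {
  co <- generateGrowthCohort(nPerGroup = 15, seed = 4)
  expect_identical(nrow(co), 30L)
  expect_identical(as.vector(table(co$group)), c(15L, 15L))
  expect_identical(as.vector(table(co$group, co$replicate)),
                   rep(5L, 6))
  ident <- generateGrowthCohort(growthEffectCtrl = 0, growthEffectExp = 0,
                                noiseSd = 0, seed = 4)
  expect_equal(ident$weight_t1_kg, ident$weight_t0_kg)
  expect_error(generateGrowthCohort(nPerGroup = 14), "divisible by 3")
  expect_error(generateGrowthCohort(meanT0Kg = -1), "meanT0Kg")
})

test_that("scene specs, ground truth and tables survive a serialization round trip", {
  dir <- withr::local_tempdir()
  spec <- randomSceneSpec(nFish = 2, seed = 5, imageShape = c(300L, 300L),
                          scaleTrue = 0.15, lengthRangeCm = c(15, 20))
  p <- file.path(dir, "spec.json")
  writeSceneSpec(spec, p)
  spec2 <- readSceneSpec(p)
  expect_equal(spec2@fish, spec@fish)
  expect_identical(renderScene(spec2)$image, renderScene(spec)$image)

  sc <- renderScene(spec)
  g <- file.path(dir, "truth.json")
  writeGroundTruth(sc$truth, g)
  tr2 <- readGroundTruth(g)
  expect_equal(length(tr2@objects), length(sc$truth@objects))
  for (i in seq_along(tr2@objects))
    expect_identical(tr2@objects[[i]]$mask, sc$truth@objects[[i]]$mask)

  tab <- generateBiomassDataset(n = 20, seed = 6)
  tp <- file.path(dir, "tab.csv")
  writeBiomassTable(tab, tp)
  expect_equal(readBiomassTable(tp), tab)

  co <- generateGrowthCohort(seed = 7)
  cp <- file.path(dir, "cohort.csv")
  writeCohortTable(co, cp)
  expect_equal(readCohortTable(cp), co)
})
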