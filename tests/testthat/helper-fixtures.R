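# Shared fixtures, all generated in code.

# Small fish-free scene with the reference circle at the centre.
referenceOnlyScene <- function(scaleTrue = 0.05, shape = c(256L, 256L),
                               seed = 1L) {
  SceneSpec(imageShape = shape, scaleTrue = scaleTrue, seed = seed)
}

# The regressor trained once on the noise-free 400-record table (seed 7,
# training defaults) and memoized for the whole suite.
cachedNoiseFreeFit <- local({
  fit <- NULL
  function() {
    if (is.null(fit))
      fit <<- fitBiomassMlp(generateBiomassDataset(n = 400, noiseCv = 0,
                                                   seed = 7),
                            seed = 7)
    fit
  }
})

# Reference + fish detections of one rendered random scene.
segmentedRandomScene <- function(seed = 3L, nFish = 5) {
  sc <- renderScene(randomSceneSpec(nFish = nFish, seed = seed))
  dets <- segmentScene(sc$image)
  list(scene = sc,
       fish = Filter(function(d) objectClass(d) == "fish", dets),
       reference = Filter(function(d) objectClass(d) == "reference", dets))
}
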