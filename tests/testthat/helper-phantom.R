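## shared fixtures built in code

## a clean (noise-free, bias-free, undeformed) subject, cached per session
cleanSubject <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSubject(
        phantomConfig(noiseSd = c(0, 0), biasAmplitude = 0, deformSd = 0),
        age = 60, subjectSeed = 1L)
    cache
  }
})

## canonical 5-channel binary class maps of the template geometry
templateClassStack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- RatioSeg:::templateGeometry(c(48L, 48L, 48L))
      m <- array(0, c(48, 48, 48, 5))
      for (j in 1:5) m[, , , j] <- (g$geo == j) + 0
      cache <<- m
    }
    cache
  }
})

## smooth random stationary velocity field (test-local; not the phantom's)
testVelocity <- function(shape = c(48L, 48L, 48L), sd0 = 0.5, smooth = 4,
                         seed = 1L) {
  set.seed(seed)
  v <- array(0, c(shape, 3L))
  for (c3 in 1:3) {
    f <- RatioSeg:::smoothArray3D(array(rnorm(prod(shape)), shape), smooth)
    v[, , , c3] <- f / sd(f) * sd0
  }
  velocityField(v)
}

## ARI of a first-pass fit against phantom ground truth
firstpassAri <- function(subject, cfg = pipelineConfig(), ...) {
  fp <- runSubjectFirstpass(subject@t1, subject@t2, subject@tissueMaps,
                            subject@brainstemMask, cfg, ...)
  truth <- maskedValues(subject@trueLabels, fp$mask)$values
  groundTruthAgreement(fp$model@labels, truth)$ari
}
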