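test_that("tissue mask thresholding keeps tissue classes and drops CSF", {
  s <- cleanSubject()
  fp <- suppressWarnings(
    runSubjectFirstpass(s@t1, s@t2, s@tissueMaps, s@brainstemMask,
                        pipelineConfig(kmeans = list(replicates = 3))))
  ## threshold below the global minimum reproduces the label mask
  m0 <- makeBrainstemTissueMask(fp$t1cal, s@brainstemMask, threshold = -1)
  expect_identical(volData(m0), volData(s@brainstemMask))
  ## default threshold 45 keeps all five classes (shell calibrates to ~55)
  m <- makeBrainstemTissueMask(fp$t1cal, s@brainstemMask)
  kept <- unique(volData(s@trueLabels)[volData(m) == 1])
  expect_setequal(kept, 1:5)
  ## raising it above the shell intensity drops the partial-volume class
  m2 <- makeBrainstemTissueMask(fp$t1cal, s@brainstemMask, threshold = 60)
  kept2 <- unique(volData(s@trueLabels)[volData(m2) == 1])
  expect_false(2 %in% kept2)
  expect_error(makeBrainstemTissueMask(fp$t1cal, s@brainstemMask, 1e9), "empty")
})

test_that("feature matrices are z-scored and affine-invariant", {
  s <- cleanSubject()
  mask <- s@brainstemMask
  set.seed(2)
  noisy <- brainVolume(volData(s@t1) + rnorm(48^3, 0, 10), s@t1@spacing)
  t2n <- brainVolume(volData(s@t2) + rnorm(48^3, 0, 4), s@t2@spacing)
  rat <- brainVolume(volData(noisy) / volData(t2n), s@t1@spacing)
  fm <- buildFeatures(noisy, t2n, rat, mask)
  expect_equal(colMeans(fm@x), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(fm@x, 2, sd), rep(1, 3), tolerance = 1e-10)
  ## single-channel variant
  fm1 <- buildFeatures(noisy, NULL, NULL, mask, channels = "T1")
  expect_equal(ncol(fm1@x), 1L)
  ## global affine rescaling of a channel leaves its z-scores unchanged
  scaled <- brainVolume(volData(noisy) * 3.7 + 11, s@t1@spacing)
  fm2 <- buildFeatures(scaled, NULL, NULL, mask, channels = "T1")
  expect_equal(fm2@x, fm1@x, tolerance = 1e-9)
  expect_error(buildFeatures(brainVolume(array(1, c(48, 48, 48))), NULL, NULL,
                             mask, channels = "T1"), "zero-variance")
})

test_that("k-means matches the brute-force optimum on a tiny instance", {
  x <- c(0, 0.1, 5.0, 5.1)
  fm <- featureMatrix(matrix(x, ncol = 1))
  model <- kmeansFit(fm, k = 2, maxIter = 100, replicates = 5, seed = 1)
  ## brute force over all 2-partitions
  best <- Inf
  for (assign in 0:(2^4 - 1)) {
    lab <- as.integer(intToBits(assign))[1:4]
    if (length(unique(lab)) < 2) next
    obj <- sum(sapply(unique(lab), function(l) {
      xs <- x[lab == l]; sum((xs - mean(xs))^2)
    }))
    best <- min(best, obj)
  }
  expect_equal(model@objective, best, tolerance = 1e-12)
  expect_equal(best, 0.01)
  expect_setequal(round(sort(model@centroids[, 1]), 3), c(0.05, 5.05))
  ## k = n gives a zero objective
  expect_equal(kmeansFit(fm, k = 4, replicates = 3, seed = 1)@objective, 0)
  expect_error(kmeansFit(fm, k = 5, seed = 1), "fewer rows")
})

test_that("k-means agrees with an independent implementation on toy data", {
  set.seed(42)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 4), ncol = 2),
             matrix(rnorm(60, -4), ncol = 2))
  ours <- kmeansFit(featureMatrix(X), k = 3, replicates = 20, seed = 7)
  ref <- stats::kmeans(X, centers = 3, nstart = 20, iter.max = 100)
  expect_equal(ours@objective, ref$tot.withinss, tolerance = 1e-6)
  ## determinism per seed; multi-replicate never worse than single
  again <- kmeansFit(featureMatrix(X), k = 3, replicates = 20, seed = 7)
  expect_identical(ours@labels, again@labels)
  single <- kmeansFit(featureMatrix(X), k = 3, replicates = 1, seed = 3)
  expect_lte(ours@objective, single@objective + 1e-12)
})

test_that("standardized distances are per-cluster min-max inverted proximities", {
  ## cluster 1 distances {1,2,3} around centroid at 0; cluster 2 zero-spread
  x <- matrix(c(-1, 2, 3, 10, 10), ncol = 1)
  labels <- c(1L, 1L, 1L, 2L, 2L)
  model <- new("ClusterModel", k = 2L, centroids = matrix(c(0, 10), ncol = 1),
               labels = labels, sqDistances = c(1, 4, 9, 0, 0),
               stdDistance = numeric(0), objective = 14, seed = 1L,
               channels = "V1", voxelIndex = 1:5, dim = c(5L, 1L, 1L))
  out <- standardizeDistances(model)
  expect_equal(out@stdDistance[1:3], c(1, 0.5, 0))
  expect_equal(out@stdDistance[4:5], c(1, 1))
})

test_that("centroid matching finds the optimal permutation", {
  mk <- function(C) new("ClusterModel", k = nrow(C), centroids = C,
                        labels = seq_len(nrow(C)),
                        sqDistances = rep(0, nrow(C)),
                        stdDistance = rep(1, nrow(C)), objective = 0,
                        seed = 1L, channels = paste0("V", seq_len(ncol(C))),
                        voxelIndex = seq_len(nrow(C)),
                        dim = c(nrow(C), 1L, 1L))
  ## identity when reference is the model itself
  m <- mk(matrix(c(0, 1), ncol = 1))
  self <- matchClusterLabels(m, m)
  expect_identical(self@labels, m@labels)
  ## two clusters that must swap
  ref <- mk(matrix(c(1.05, -0.02), ncol = 1))
  sw <- matchClusterLabels(m, ref)
  expect_identical(sw@labels, c(2L, 1L))
  expect_equal(sw@centroids[, 1], c(1, 0))
  ## k = 5 random centroids: equals the brute-force assignment over 5! perms
  set.seed(11)
  A <- matrix(rnorm(15), 5, 3)
  B <- A[sample(5), ] + matrix(rnorm(15, 0, 0.05), 5, 3)
  ma <- mk(A); colnames(A) <- colnames(B) <- NULL
  mb <- new("ClusterModel", k = 5L, centroids = B, labels = 1:5,
            sqDistances = rep(0, 5), stdDistance = rep(1, 5), objective = 0,
            seed = 1L, channels = ma@channels, voxelIndex = 1:5,
            dim = c(5L, 1L, 1L))
  matched <- matchClusterLabels(ma, mb)
  cost <- function(perm) sum(sqrt(rowSums((A - B[perm, ])^2)))
  ## recover the permutation actually applied: label i -> matched@labels[i]
  applied <- matched@labels
  perms <- RatioSeg:::permutations(5)
  allCosts <- apply(perms, 1, cost)
  expect_equal(cost(applied), min(allCosts), tolerance = 1e-12)
  expect_error(matchClusterLabels(ma, mk(matrix(0:1, ncol = 1))), "differ")
})

test_that("binary maps partition the analysis mask", {
  s <- cleanSubject()
  fp <- suppressWarnings(
    runSubjectFirstpass(s@t1, s@t2, s@tissueMaps, s@brainstemMask,
                        pipelineConfig(kmeans = list(replicates = 5))))
  total <- Reduce("+", lapply(fp$binaryMaps, volData))
  expect_identical(total, volData(fp$mask))
  ## noiseless phantom: maps equal the ground-truth classes up to relabeling
  truth <- maskedValues(s@trueLabels, fp$mask)$values
  expect_equal(groundTruthAgreement(fp$model@labels, truth)$ari, 1)
})

test_that("label matching aligns cluster numbering across a clean cohort", {
  cfg <- phantomConfig(noiseSd = c(0, 0), biasAmplitude = 0, deformSd = 0)
  coh <- generateCohort(cfg, 3, seed = 2)
  pc <- pipelineConfig(kmeans = list(replicates = 5))
  fits <- list()
  for (i in 1:3) {
    s <- coh[[i]]
    fits[[i]] <- suppressWarnings(runSubjectFirstpass(
      s@t1, s@t2, s@tissueMaps, s@brainstemMask, pc,
      reference = if (i > 1) fits[[1]]$model else NULL, seed = i))
  }
  ## identical geometry: after matching, every subject labels each true class
  ## with the same cluster number
  lab1 <- maskedValues(coh[[1]]@trueLabels, fits[[1]]$mask)$values
  map1 <- tapply(fits[[1]]$model@labels, lab1, function(v) unique(v)[1])
  for (i in 2:3) {
    labi <- maskedValues(coh[[i]]@trueLabels, fits[[i]]$mask)$values
    mapi <- tapply(fits[[i]]$model@labels, labi, function(v) unique(v)[1])
    expect_identical(mapi, map1)
  }
})
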