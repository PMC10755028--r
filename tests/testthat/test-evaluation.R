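## exhaustive silhouette oracle: direct double loop over all pairs
silhouetteOracle <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
    own <- labels == labels[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(tapply(di[!own], labels[!own], mean))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

test_that("silhouettes equal the exhaustive pairwise oracle", {
  set.seed(4)
  X <- rbind(matrix(rnorm(80, 0, 0.5), ncol = 2),
             matrix(rnorm(80, 4, 0.5), ncol = 2),
             matrix(rnorm(40, c(0, 6), 0.5), ncol = 2))
  labels <- rep(1:3, c(40, 40, 20))
  s <- silhouetteValues(featureMatrix(X), labels, sampleSize = 1000, seed = 1)
  expect_equal(s, silhouetteOracle(X, labels), tolerance = 1e-9)

  ## two tight, well-separated 1D clusters: all coefficients ~ 1
  x2 <- matrix(c(0, 0.01, 10, 10.01), ncol = 1)
  s2 <- silhouetteValues(featureMatrix(x2), c(1, 1, 2, 2), 10, 1)
  expect_true(all(s2 > 0.99))
  ## a point equidistant between two symmetric clusters scores 0
  x3 <- matrix(c(-1, 1, 0, 9, 11, 10), ncol = 1)
  s3 <- silhouetteValues(featureMatrix(x3), c(1, 1, 1, 2, 2, 2), 10, 1)
  expect_equal(s3[3], (10 - 1) / 10, tolerance = 1e-9)  # a=1, b=10
  expect_error(silhouetteValues(featureMatrix(x2), rep(1, 4), 10, 1),
               "2 clusters")
  ## subsampling is seeded and capped
  set.seed(9)
  Xl <- matrix(rnorm(1200), ncol = 2)
  ll <- rep(1:2, 300)
  sa <- silhouetteValues(featureMatrix(Xl), ll, sampleSize = 100, seed = 5)
  sb <- silhouetteValues(featureMatrix(Xl), ll, sampleSize = 100, seed = 5)
  expect_length(sa, 100L)
  expect_identical(sa, sb)
})

test_that("misclassification index counts voxels outside their thresholded prior", {
  ## cluster 1 has 4 voxels, one of them below the 0.3 prior; others clean
  labels <- c(1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L)
  P <- matrix(0, 8, 5)
  P[1:4, 1] <- c(0.8, 0.6, 0.5, 0.1)   # one below 0.3
  P[5, 2] <- 0.9; P[6, 3] <- 0.9; P[7, 4] <- 0.9; P[8, 5] <- 0.9
  maps <- array(0, c(8, 1, 1, 5))
  for (j in 1:5) maps[, , , j] <- P[, j]
  pri <- priorSet(maps, frame = "subject")
  model <- new("ClusterModel", k = 5L, centroids = matrix(0, 5, 1),
               labels = labels, sqDistances = rep(0, 8),
               stdDistance = c(0.9, 1, 1, 0.7, 1, 1, 1, 1), objective = 0,
               seed = 1L, channels = "V1", voxelIndex = 1:8,
               dim = c(8L, 1L, 1L))
  expect_equal(misclassificationIndex(model, pri), mean(c(0.25, 0, 0, 0, 0)))
  ## perfect one-hot priors give a zero index
  P1 <- matrix(0, 8, 5); P1[cbind(1:8, labels)] <- 1
  maps1 <- array(0, c(8, 1, 1, 5))
  for (j in 1:5) maps1[, , , j] <- P1[, j]
  expect_equal(misclassificationIndex(model, priorSet(maps1, frame = "subject")),
               0)
  ## misclassification distance averages the proximity of misclassified voxels
  expect_equal(misclassificationDistance(model, pri), 0.7)
  expect_warning(
    md0 <- misclassificationDistance(model, priorSet(maps1, frame = "subject")),
    "undefined")
  expect_equal(md0, 0)
})

test_that("subthreshold silhouette index is the fraction below the cutoff", {
  expect_equal(subthresholdSilhouetteIndex(c(0.9, 0.5, 0.7, 0.4)), 0.5)
  expect_equal(subthresholdSilhouetteIndex(c(0.7, 0.8, 0.99)), 0)
  expect_equal(subthresholdSilhouetteIndex(c(0.59, 0.61), cutoff = 0.6), 0.5)
  expect_error(subthresholdSilhouetteIndex(numeric(0)), "empty")
})

test_that("ground-truth agreement behaves like ARI plus matched Dice", {
  lab <- rep(1:5, each = 50)
  same <- groundTruthAgreement(lab, lab)
  expect_equal(same$ari, 1)
  expect_equal(unname(same$dice), rep(1, 5))
  ## independent random labelings have ARI ~ 0
  set.seed(6)
  a <- sample.int(5, 5000, replace = TRUE)
  b <- sample.int(5, 5000, replace = TRUE)
  expect_lt(abs(groundTruthAgreement(a, b)$ari), 0.02)
  ## a full swap of two classes is repaired by the optimal matching
  swapped <- lab
  swapped[lab == 1] <- 2L
  swapped[lab == 2] <- 1L
  sw <- groundTruthAgreement(swapped, lab)
  expect_equal(unname(sw$dice), rep(1, 5))
  expect_equal(sw$ari, 1)   # ARI is permutation invariant
  ## indices are invariant under consistent relabeling
  perm <- c(3L, 5L, 1L, 2L, 4L)
  expect_equal(groundTruthAgreement(perm[lab], lab)$ari, 1)
})

test_that("quality reports bundle the three indices per variant", {
  cfg <- phantomConfig(noiseSd = c(60, 8), deformSd = 0, seed = 3)
  coh <- generateCohort(cfg, 3, seed = 17)
  pc <- pipelineConfig(kmeans = list(replicates = 10),
                       silhouette = list(sampleSize = 1500L, cutoff = 0.6))
  rep <- compareVariants(coh, pc,
                         variants = list("T1+T2+RATIO" = c("T1", "T2", "RATIO"),
                                         "T1" = "T1"))
  expect_equal(nrow(rep), 6L)
  expect_true(all(rep$misclassification_index >= 0 &
                    rep$misclassification_index <= 1))
  expect_true(all(rep$subthreshold_silhouette_index >= 0 &
                    rep$subthreshold_silhouette_index <= 1))
  expect_true(all(rep$misclassification_distance >= 0 &
                    rep$misclassification_distance <= 1))
})
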