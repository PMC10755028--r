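## small helper: PriorSet from an explicit per-voxel probability matrix
priorsFromMatrix <- function(P, shape = c(nrow(P), 1L, 1L)) {
  maps <- array(0, c(shape, ncol(P)))
  for (j in seq_len(ncol(P))) maps[, , , j] <- array(P[, j], shape)
  priorSet(maps, frame = "subject")
}

## minimal ClusterModel over n voxels of a flat grid
flatModel <- function(labels, std = rep(1, length(labels)), k = 5L) {
  new("ClusterModel", k = k, centroids = matrix(0, k, 1),
      labels = as.integer(labels), sqDistances = rep(0, length(labels)),
      stdDistance = std, objective = 0, seed = 1L, channels = "V1",
      voxelIndex = seq_along(labels), dim = c(length(labels), 1L, 1L))
}

test_that("priors are voxelwise cluster frequencies", {
  one <- array(0, c(4, 1, 1, 5)); one[, , , 2] <- 1
  other <- one
  other[1, , , 2] <- 0; other[1, , , 3] <- 1   # disagree at voxel 1
  p <- buildPriors(list(one, one))
  expect_identical(p@maps, one)
  p2 <- buildPriors(list(one, other))
  expect_equal(p2@maps[1, 1, 1, 2], 0.5)
  expect_equal(p2@maps[1, 1, 1, 3], 0.5)
  ## averaging one-hot maps preserves the per-voxel partition of unity
  expect_equal(apply(p2@maps, 1:3, sum), array(1, c(4, 1, 1)))
  expect_error(buildPriors(list(one)), "at least 2")
  four <- one[, , , 1:4, drop = FALSE]
  expect_error(buildPriors(list(four, four)), "5 cluster")
})

test_that("prior projection warps channels and keeps probabilities in range", {
  s <- cleanSubject()
  maps <- templateClassStack()
  priors <- priorSet(maps)
  shape <- c(48L, 48L, 48L)
  id <- exponentiate(velocityField(array(0, c(shape, 3))),
                     from = "subject", to = "template")
  pid <- projectPriors(priors, id)
  expect_equal(pid@maps, maps, tolerance = 1e-12)
  expect_identical(pid@frame, "subject")

  v <- testVelocity(shape, sd0 = 0.5, smooth = 4, seed = 4)
  fwd <- exponentiate(v)
  inv <- invertDeformation(fwd)
  ## realistic smooth priors: blurred class frequencies
  sm <- array(0, dim(maps))
  for (j in 1:5) sm[, , , j] <- RatioSeg:::smoothArray3D(maps[, , , j], 1.5)
  priorsSm <- priorSet(sm)
  proj <- projectPriors(priorsSm, inv)
  expect_gte(min(proj@maps), 0)
  expect_lte(max(proj@maps), 1)
  ## round-trip template -> subject -> template changes the in-mask mean < 2%
  back <- projectPriors(proj, fwd)
  msk <- volData(s@brainstemMask) == 1
  relerr <- sapply(1:5, function(j)
    abs(mean(back@maps[, , , j][msk]) - mean(sm[, , , j][msk])) /
      mean(sm[, , , j][msk]))
  expect_lt(mean(relerr), 0.02)
})

test_that("consistency reassignment applies the two printed rules", {
  ## all voxels assigned to cluster 1; columns are cluster prior probabilities
  P <- rbind(
    c(0.10, 0.76, 0, 0, 0),   # rule 1: alt=2 at 0.76 >= 0.75 -> move
    c(0.35, 0.55, 0, 0, 0),   # rule 2 only: margin 0.20, 0.55 < 0.75 -> move
    c(0.44, 0.55, 0, 0, 0),   # neither: 0.55 < 0.75, margin 0.11 -> keep
    c(0.80, 0.10, 0, 0, 0))   # consistent (own cluster is argmax) -> keep
  model <- flatModel(c(1L, 1L, 1L, 1L))
  pri <- priorsFromMatrix(P)
  out <- consistencyReassign(model, pri)
  expect_identical(as.vector(out@labels)[1:4], c(2L, 2L, 1L, 1L))
  log <- attr(out@labels, "reassignLog")
  expect_equal(log$n_reassigned, 2L)
  expect_equal(log$n_rule1, 1L)
  ## the margin rule is inclusive at exactly 0.20 and rule 1 at exactly 0.75
  Pedge <- rbind(c(0.30, 0.50, 0.2, 0, 0), c(0.25, 0.75, 0, 0, 0))
  oute <- consistencyReassign(flatModel(c(1L, 1L)), priorsFromMatrix(Pedge))
  expect_identical(as.vector(oute@labels), c(2L, 2L))
})

test_that("reassignment grows monotonically as thresholds are lowered", {
  set.seed(8)
  n <- 500
  P <- matrix(runif(5 * n), n, 5)
  P <- P / rowSums(P) * 0.97   # strictly below 1 so thresholds of 1 never fire
  model <- flatModel(sample.int(5, n, replace = TRUE))
  pri <- priorsFromMatrix(P)
  moved <- function(alt, marg) {
    out <- consistencyReassign(model, pri, alt, marg)
    which(out@labels != model@labels)
  }
  none <- moved(1, 1)
  mid <- moved(0.75, 0.20)
  loose <- moved(0.50, 0.10)
  expect_length(none, 0L)
  expect_true(all(mid %in% loose))
  expect_gte(length(loose), length(mid))
})

test_that("clean first-pass segmentations are left untouched by reassignment", {
  cfg <- phantomConfig(noiseSd = c(0, 0), biasAmplitude = 0, deformSd = 0)
  coh <- generateCohort(cfg, 3, seed = 21)
  pc <- pipelineConfig(kmeans = list(replicates = 5))
  fits <- list()
  for (i in 1:3) {
    s <- coh[[i]]
    fits[[i]] <- suppressWarnings(runSubjectFirstpass(
      s@t1, s@t2, s@tissueMaps, s@brainstemMask, pc,
      reference = if (i > 1) fits[[1]]$model else NULL, seed = i))
  }
  priors <- buildPriors(lapply(fits, function(x)
    RatioSeg:::stackMaps(x$binaryMaps)))
  priors@frame <- "subject"
  for (i in 1:3) {
    out <- consistencyReassign(fits[[i]]$model, priors)
    expect_identical(as.vector(out@labels), as.vector(fits[[i]]$model@labels))
  }
})

test_that("final probabilities are the binary x prior x proximity product", {
  ## 3 voxels, 5 clusters; voxel 1 in cluster 1, voxel 2 in cluster 2,
  ## voxel 3 unassigned (no binary support)
  shape <- c(3L, 1L, 1L)
  bins <- lapply(1:5, function(j) {
    m <- array(0, shape)
    if (j <= 2) m[j, 1, 1] <- 1
    maskVolume(m)
  })
  P <- rbind(c(0.8, 0.1, 0, 0, 0),
             c(0.2, 0.5, 0, 0, 0),
             c(0.9, 0.1, 0, 0, 0))
  pri <- priorsFromMatrix(P, shape)
  model <- flatModel(c(1L, 2L, 3L), std = c(0.9, 1.0, 0.5))
  fs <- toProbabilistic(bins, pri, model)
  expect_equal(fs@maps[1, 1, 1, 1], 1 * 0.8 * 0.9)   # 0.72
  expect_equal(fs@maps[2, 1, 1, 2], 1 * 0.5 * 1.0)
  expect_equal(sum(fs@maps[3, 1, 1, ]), 0)           # no support -> all zero
  expect_equal(volData(fs@hardLabels)[, 1, 1], c(1, 2, 0))
  ## identity weights (prior 1 on the supporting cluster, proximity 1)
  onehot <- matrix(0, 3, 5); onehot[1, 1] <- 1; onehot[2, 2] <- 1
  onehot[3, 3] <- 1
  fs1 <- toProbabilistic(bins, priorsFromMatrix(onehot, shape),
                         flatModel(c(1L, 2L, 3L), std = c(1, 1, 1)))
  for (j in 1:5)
    expect_equal(array(fs1@maps[, , , j], shape), volData(bins[[j]]))
})

test_that("final segmentations serialize to NIfTI and JSON", {
  dir <- withr::local_tempdir()
  shape <- c(3L, 1L, 1L)
  bins <- lapply(1:5, function(j) {
    m <- array(0, shape); if (j == 1) m[, 1, 1] <- 1
    maskVolume(m)
  })
  pri <- priorsFromMatrix(matrix(0.2, 3, 5), shape)
  fs <- toProbabilistic(bins, pri, flatModel(rep(1L, 3)))
  writeFinalSegmentation(fs, dir, prefix = "s1")
  expect_true(file.exists(file.path(dir, "s1_cluster1.nii.gz")))
  expect_true(file.exists(file.path(dir, "s1_labels.nii.gz")))
  expect_true(file.exists(file.path(dir, "s1_reassign.json")))
})
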