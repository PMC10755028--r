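test_that("exponentiation satisfies the group identities", {
  shape <- c(24L, 24L, 24L)
  ## exp(0) = identity
  d0 <- exponentiate(velocityField(array(0, c(shape, 3))))
  expect_true(all(d0@disp == 0))
  ## spatially constant velocity integrates to a pure translation (interior)
  vt <- array(0, c(shape, 3)); vt[, , , 1] <- 0.7
  dt <- exponentiate(velocityField(vt))
  expect_equal(mean(dt@disp[5:20, 5:20, 5:20, 1]), 0.7, tolerance = 1e-6)
  expect_equal(max(abs(dt@disp[5:20, 5:20, 5:20, 2:3])), 0)
  expect_error(exponentiate(velocityField(vt), nSteps = 2), "nSteps")
})

test_that("inverse composes with the forward map to near-identity", {
  v <- testVelocity(c(48L, 48L, 48L), sd0 = 0.5, smooth = 4, seed = 2)
  d <- exponentiate(v)
  di <- invertDeformation(d)
  comp <- RatioSeg:::composeDisp(di@disp, d@disp)
  mag <- array(sqrt(rowSums(matrix(comp, ncol = 3)^2)), c(48, 48, 48))
  ## measured over the interior (boundary voxels leave the field of view)
  expect_lt(mean(mag[5:44, 5:44, 5:44]), 0.05)
  ## identity inverts to identity; translation to the negated translation
  id <- exponentiate(velocityField(array(0, c(8, 8, 8, 3))))
  expect_true(all(invertDeformation(id)@disp == 0))
  vt <- array(0, c(24, 24, 24, 3)); vt[, , , 2] <- -0.5
  ti <- invertDeformation(exponentiate(velocityField(vt)))
  expect_equal(mean(ti@disp[5:20, 5:20, 5:20, 2]), 0.5, tolerance = 1e-6)
  ## numeric fixed-point route (velocity discarded) agrees
  dnum <- new("DeformationField", disp = d@disp, from = "template",
              to = "subject", velocity = NULL)
  din <- invertDeformation(dnum)
  comp2 <- RatioSeg:::composeDisp(din@disp, d@disp)
  mag2 <- array(sqrt(rowSums(matrix(comp2, ncol = 3)^2)), c(48, 48, 48))
  expect_lt(mean(mag2[5:44, 5:44, 5:44]), 0.05)
})

test_that("Jacobian determinants reproduce closed forms", {
  shape <- c(24L, 24L, 24L)
  id <- exponentiate(velocityField(array(0, c(shape, 3))))
  expect_equal(volData(jacobianDeterminant(id)), array(1, shape))
  ## pure translation: J = 1 in the interior
  vt <- array(0, c(shape, 3)); vt[, , , 1] <- 1.2
  jt <- volData(jacobianDeterminant(exponentiate(velocityField(vt))))
  expect_equal(jt[5:20, 5:20, 5:20], array(1, c(16, 16, 16)), tolerance = 1e-3)
  ## uniform 0.9 scaling per axis: J = 0.729 in the interior
  co <- RatioSeg:::gridCoords(shape); ctr <- (shape + 1) / 2
  vs <- array(0, c(shape, 3))
  for (c3 in 1:3) vs[, , , c3] <- log(0.9) * (co[, c3] - ctr[c3])
  js <- volData(jacobianDeterminant(exponentiate(velocityField(vs))))
  expect_equal(mean(js[8:17, 8:17, 8:17]), 0.9^3, tolerance = 1e-3)
})

test_that("warping matches direct array manipulation", {
  s <- cleanSubject()
  shape <- c(48L, 48L, 48L)
  id <- exponentiate(velocityField(array(0, c(shape, 3))))
  expect_equal(volData(warpVolume(s@t1, id)), volData(s@t1), tolerance = 1e-12)
  ## integer translation with nearest interpolation = exact array shift
  dtr <- new("DeformationField",
             disp = array(rep(c(2, 0, 0), each = prod(shape)), c(shape, 3)),
             from = "template", to = "subject", velocity = NULL)
  w <- warpVolume(s@trueLabels, dtr, interpolation = "nearest")
  expect_identical(volData(w)[1:46, , ], volData(s@trueLabels)[3:48, , ])
  ## probabilities stay in [0,1] under linear interpolation
  v <- testVelocity(shape, sd0 = 1, smooth = 4, seed = 3)
  wp <- warpVolume(s@tissueMaps$gm, exponentiate(v))
  expect_gte(min(volData(wp)), 0)
  expect_lte(max(volData(wp)), 1 + 1e-12)
})

test_that("pairwise registration recovers identity and translations", {
  maps <- templateClassStack()
  ## moving = fixed: near-zero velocity
  v0 <- registerPair(maps, maps, iters = c(5, 5, 3))
  expect_lt(mean(abs(v0@v)), 0.01)
  ## 2-voxel translation recovered within 0.2 voxel over the tissue
  mv <- array(0, dim(maps)); mv[1:46, , , ] <- maps[3:48, , , ]
  v <- registerPair(mv, maps)
  d <- exponentiate(v)
  g <- RatioSeg:::templateGeometry(c(48L, 48L, 48L))
  tissue <- g$geo > 0 & g$geo < 6
  expect_lt(mean(abs(d@disp[, , , 1][tissue] + 2)), 0.2)
  expect_error(registerPair(mv, maps[, , 1:24, ]), "differ")
})

test_that("registration recovers known diffeomorphisms to subvoxel accuracy", {
  maps <- templateClassStack()
  g <- RatioSeg:::templateGeometry(c(48L, 48L, 48L))
  tissue <- as.vector(g$geo > 0 & g$geo < 6)
  ## phantom-scale fields; tangential motion along flat boundaries is only
  ## partly observable, so the contract is on the typical (median over seeds)
  ## per-voxel endpoint error
  meds <- sapply(1:5, function(seed) {
    v <- testVelocity(c(48L, 48L, 48L), sd0 = 0.5, smooth = 4, seed = seed)
    dtrue <- exponentiate(v)
    dinv <- invertDeformation(dtrue)
    moved <- array(0, dim(maps))
    for (j in 1:5)
      moved[, , , j] <- volData(warpVolume(brainVolume(maps[, , , j]), dinv))
    vrec <- registerPair(moved, maps, iters = c(60, 45, 25), smooth = 1.6)
    drec <- exponentiate(vrec)
    ep <- sqrt(rowSums((matrix(drec@disp, ncol = 3) -
                          matrix(dtrue@disp, ncol = 3))^2))
    median(ep[tissue])
  })
  expect_lt(median(meds), 0.5)
  ## SSD trace is non-increasing (up to the 1% rollback tolerance) within a
  ## single-level registration
  mv <- array(0, dim(maps)); mv[1:46, , , ] <- maps[3:48, , , ]
  v1 <- registerPair(mv, maps, levels = 1L, iters = 25L)
  tr <- attr(v1@v, "ssd")
  expect_true(all(diff(tr) <= pmax(1e-12, 0.01 * head(tr, -1))))
})

test_that("template building tightens identical and translated cohorts", {
  maps <- templateClassStack()
  ## identical subjects: template equals them, deformations ~ identity
  tpl <- buildGroupTemplate(list(maps, maps), nIters = 1, iters = c(5, 5, 3))
  expect_equal(tpl@template, maps, tolerance = 1e-3)
  expect_lt(mean(abs(tpl@forward[[1]]@disp)), 0.02)
  ## two translated copies: registered average is sharper than the raw one
  m1 <- array(0, dim(maps)); m1[1:46, , , ] <- maps[3:48, , , ]
  m2 <- array(0, dim(maps)); m2[3:48, , , ] <- maps[1:46, , , ]
  tpl2 <- buildGroupTemplate(list(m1, m2), nIters = 2)
  raw <- (m1 + m2) / 2
  sharp <- function(x) mean(pmax(x[, , , 1], x[, , , 2], x[, , , 3],
                                 x[, , , 4], x[, , , 5]) > 0.9)
  expect_gt(sharp(tpl2@template), sharp(raw))
  ## group SSD non-increasing over outer iterations
  expect_true(all(diff(tpl2@ssdTrace) <= 1e-9))
  expect_error(buildGroupTemplate(list(maps)), "at least 2")
})

test_that("template building recovers per-subject atrophy factors", {
  ## wider-than-default shape variation so the true volume factors span a
  ## range the recovered ROI means must track
  cfg <- phantomConfig(noiseSd = c(0, 0), biasAmplitude = 0, deformSd = 0.5)
  ages <- seq(36, 100, length.out = 8)
  coh <- lapply(1:8, function(i) generateSubject(cfg, ages[i], 500 + i))
  stacks <- lapply(coh, function(s) {
    m <- array(0, c(48, 48, 48, 5))
    for (j in 1:5) m[, , , j] <- (volData(s@trueLabels) == j) + 0
    m
  })
  tpl <- buildGroupTemplate(stacks, nIters = 2, iters = c(40, 30, 15))
  atlas <- templateAtlas()
  sn <- volData(atlas) %in% 1:2
  trueJ <- sapply(coh, function(s)
    mean(volData(jacobianDeterminant(s@trueDeformation))[sn]))
  recJ <- sapply(tpl@forward, function(d)
    mean(volData(jacobianDeterminant(d))[sn]))
  ## recovered ROI-mean Jacobians track the ground-truth volume factors of
  ## the structured (boundary-carrying) atrophy ROIs
  expect_gte(cor(trueJ, recJ), 0.9)
})
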