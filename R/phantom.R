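#' Synthetic brainstem phantom configuration
#'
#' Defaults define the study conditions of the synthetic cohorts. The five
#' tissue classes follow the anatomy of the five-cluster solution: class 1 an
#' iron-rich/white class (brightest T1, darkest T2), class 2 the
#' partial-volume shell at the CSF/tissue boundary, classes 3 and 5 gray
#' classes (a dorsal PAG-like column and ventral nuclei), class 4 the
#' predominantly white mixed class. T1 means are ordered
#' iron > white > gray > shell > CSF and T2 means reversed; the default T1
#' white-matter/CSF modes (600/120) and T2 modes (80/400) sit at typical
#' arbitrary-unit scanner values. Channel noise is additive Gaussian with a
#' constant per-channel SD (thermal-noise convention), independent between
#' T1 and T2; the defaults (30 and 4 intensity units) put the white-matter
#' SNR of both channels at 20. Residual bias-field amplitude is 5\%. Random
#' diffeomorphic shape variation has per-component SD 0.35 voxels at
#' smoothness 4 voxels (about 0.55 voxels median displacement -- the residual
#' anatomic variability left after upstream spatial normalization to a
#' common space), and the designated atrophy ROIs (left and right SN-like
#' regions) contract linearly by 0.3\%/year of age.
#'
#' @param shape grid dims (default 48^3).
#' @param classMeansT1,classMeansT2 named per-class mean intensities.
#' @param csfT1,csfT2 CSF-rim intensities; \code{bgT1,bgT2} background.
#' @param noiseSd additive noise SD per channel (T1, T2), intensity units.
#' @param biasAmplitude,biasSmooth multiplicative bias-field parameters.
#' @param deformSd,deformSmooth random velocity magnitude/scale (voxels).
#' @param ageBeta per-year fractional volume change of atrophy ROIs.
#' @param ageCenter age at which the atrophy factor equals 1 (default 60).
#' @param atrophyRois ROI names receiving the age effect.
#' @param seed master seed.
#' @return A \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(shape = c(48L, 48L, 48L),
                          classMeansT1 = c(iron = 780, shell = 330,
                                           gray_pag = 480, white = 600,
                                           gray_nuclei = 400),
                          classMeansT2 = c(iron = 45, shell = 320,
                                           gray_pag = 140, white = 80,
                                           gray_nuclei = 220),
                          csfT1 = 120, csfT2 = 400, bgT1 = 50, bgT2 = 30,
                          noiseSd = c(30, 4), biasAmplitude = 0.05,
                          biasSmooth = 12, deformSd = 0.35, deformSmooth = 4,
                          ageBeta = -0.003, ageCenter = 60,
                          atrophyRois = c("SN_L", "SN_R"), seed = 1L) {
  if (length(noiseSd) == 1L) noiseSd <- rep(noiseSd, 2L)
  ## class order fixed to (iron, shell, gray_pag, white, gray_nuclei)
  ord <- c("iron", "shell", "gray_pag", "white", "gray_nuclei")
  new("PhantomConfig", shape = as.integer(shape), nClasses = 5L,
      classMeansT1 = classMeansT1[ord], classMeansT2 = classMeansT2[ord],
      csfT1 = csfT1, csfT2 = csfT2, bgT1 = bgT1, bgT2 = bgT2,
      noiseSd = noiseSd, biasAmplitude = biasAmplitude,
      biasSmooth = biasSmooth, deformSd = deformSd,
      deformSmooth = deformSmooth, ageBeta = ageBeta, ageCenter = ageCenter,
      atrophyRois = atrophyRois, seed = as.integer(seed))
}

## voxel spacing of the phantoms (mm), matching 0.8 mm isotropic acquisition
phantomSpacing <- c(0.8, 0.8, 0.8)

#' Canonical template geometry
#'
#' Deterministic label geometry in template space: an ellipsoidal brainstem
#' (normalized radius rho <= 1) whose outer 15\% is the partial-volume shell
#' (class 2), with interior iron-rich blobs (class 1), a dorsal gray column
#' (class 3), ventral gray nuclei (class 5) and the remaining interior white
#' (class 4); a pure-CSF rim (code 6) surrounds the ellipsoid. The ROI atlas
#' contains eight spheric/cylindric regions; SN_L and SN_R coincide with the
#' iron-rich blobs and are the designated atrophy targets.
#'
#' @param shape grid dims.
#' @return list with \code{geo} (3D array coded 0 background, 1..5 classes,
#'   6 CSF rim), \code{atlas} (3D array 0..8), \code{roiNames}, and
#'   \code{roiCenters} (8 x 3 matrix, voxel coords).
#' @export
templateGeometry <- function(shape = c(48L, 48L, 48L)) {
  ctr <- (shape + 1) / 2
  sc <- shape / 48          # radii scale with the grid
  co <- gridCoords(shape)
  dx <- co[, 1] - ctr[1]; dy <- co[, 2] - ctr[2]; dz <- co[, 3] - ctr[3]
  rx <- 14 * sc[1]; ry <- 12 * sc[2]; rz <- 19 * sc[3]
  rho <- sqrt((dx / rx)^2 + (dy / ry)^2 + (dz / rz)^2)
  sphere <- function(cx, cy, cz, r)
    (dx - cx)^2 + (dy - cy)^2 + (dz - cz)^2 <= r^2
  inTissue <- rho <= 1
  inRim <- rho > 1 & rho <= 1.18
  shell <- inTissue & rho > 0.90
  interior <- inTissue & !shell
  iron <- interior & (sphere(-6, 0, 9, 4.5) | sphere(6, 0, 9, 4.5))
  pag <- interior & ((dx^2 + (dy - 4)^2) <= 6.5^2) & dz >= -2 & dz <= 16 & !iron
  nuclei <- interior & !iron & !pag &
    (((dx^2 + (dy + 3)^2) <= 7^2 & dz >= -17 & dz <= -1) |
       sphere(-7, 0, -6, 3.5) | sphere(7, 0, -6, 3.5) | sphere(0, 3, -13, 3))
  geo <- numeric(nrow(co))
  geo[inRim] <- 6
  geo[interior] <- 4
  geo[nuclei] <- 5
  geo[pag] <- 3
  geo[iron] <- 1
  geo[shell] <- 2
  roiNames <- c("SN_L", "SN_R", "PAG", "RPO", "OI_L", "OI_R", "PN", "MRF")
  roiCenters <- rbind(c(-6, 0, 9), c(6, 0, 9), c(0, 4, 8), c(0, -4, 5),
                      c(-5.5, 1, -10), c(5.5, 1, -10), c(0, -5, -5),
                      c(0, 4, -14))
  atlas <- numeric(nrow(co))
  roiDef <- list(
    sphere(-6, 0, 9, 4.5),
    sphere(6, 0, 9, 4.5),
    (dx^2 + (dy - 4)^2) <= 3.2^2 & dz >= 3 & dz <= 14,
    sphere(0, -4, 5, 3.5),
    sphere(-5.5, 1, -10, 3.5),
    sphere(5.5, 1, -10, 3.5),
    sphere(0, -5, -5, 3.5),
    sphere(0, 4, -14, 3))
  for (l in rev(seq_along(roiDef)))       # lower index wins on overlap
    atlas[roiDef[[l]] & inTissue] <- l
  list(geo = array(geo, shape), atlas = array(atlas, shape),
       roiNames = roiNames,
       roiCenters = sweep(roiCenters, 2L, ctr, "+"))
}

#' The phantom ROI atlas in template space
#'
#' @param shape grid dims.
#' @return A \linkS4class{LabelVolume} (frame "template").
#' @export
templateAtlas <- function(shape = c(48L, 48L, 48L)) {
  g <- templateGeometry(shape)
  labelVolume(g$atlas, g$roiNames, spacing = phantomSpacing,
              frame = "template")
}

#' Smooth multiplicative bias field
#'
#' Smoothed white noise, centered to mean 1 and scaled so deviations stay
#' within [-amplitude, +amplitude]. Deterministic per seed; amplitude 0
#' returns a field identically 1.
#'
#' @param shape grid dims.
#' @param amplitude max fractional deviation, in [0,1).
#' @param smooth Gaussian scale in voxels.
#' @param seed RNG seed.
#' @return A \linkS4class{BrainVolume}.
#' @export
generateBiasField <- function(shape, amplitude, smooth, seed) {
  if (amplitude >= 1 || amplitude < 0) stop("amplitude must lie in [0,1)")
  if (amplitude == 0)
    return(brainVolume(array(1, shape), phantomSpacing))
  set.seed(as.integer(seed))
  f <- smoothArray3D(array(stats::rnorm(prod(shape)), shape), smooth)
  f <- f - mean(f)
  mx <- max(abs(f))
  if (mx > 0) f <- f / mx * amplitude
  brainVolume(1 + f, phantomSpacing)
}

## random smooth stationary velocity field (voxel units)
randomVelocity <- function(shape, sd, smooth, seed) {
  v <- array(0, c(shape, 3L))
  if (sd > 0) {
    set.seed(as.integer(seed))
    for (c3 in 1:3) {
      f <- smoothArray3D(array(stats::rnorm(prod(shape)), shape), smooth)
      v[, , , c3] <- f / stats::sd(f) * sd
    }
  }
  v
}

## age-linked contraction velocity: divergence log(f) inside each atrophy
## ROI (f the linear volume factor), tapered smoothly at the ROI boundary
atrophyVelocity <- function(shape, atlas, roiNames, roiCenters, atrophyRois,
                            volumeFactor) {
  v <- array(0, c(shape, 3L))
  if (volumeFactor == 1) return(v)
  co <- gridCoords(shape)
  for (roi in atrophyRois) {
    l <- match(roi, roiNames)
    if (is.na(l)) stop("unknown atrophy ROI: ", roi)
    ind <- array(0, shape)
    ind[atlas == l] <- 1
    ## dilate ~4-5 voxels then smooth so the weight is exactly 1 across the
    ## whole ROI and the taper lies outside it: the divergence (hence the
    ## Jacobian) then equals the nominal volume factor everywhere in the ROI
    dil <- (smoothArray3D(ind, 2.0) > 0.02) + 0
    w <- smoothArray3D(dil, 1.5)
    w[w > 1] <- 1
    alpha <- log(volumeFactor) / 3
    for (c3 in 1:3)
      v[, , , c3] <- v[, , , c3] +
        alpha * as.numeric(w) * (co[, c3] - roiCenters[l, c3])
  }
  v
}

#' Generate one synthetic subject
#'
#' The canonical template geometry is warped by a random smooth
#' diffeomorphism composed (at the velocity level) with an age-dependent
#' contraction of the designated atrophy ROIs whose local volume factor is
#' 1 + ageBeta (age - ageCenter). Voxel intensities are
#' class mean x bias + noise with independent additive Gaussian noise per
#' channel. Full ground truth (labels, atlas, deformation) is recorded.
#'
#' @param cfg a \linkS4class{PhantomConfig}.
#' @param age age in years (0..120).
#' @param subjectSeed per-subject seed.
#' @param id subject identifier.
#' @return A \linkS4class{SubjectGroundTruth}.
#' @export
generateSubject <- function(cfg, age, subjectSeed, id = sprintf("s%04d", subjectSeed %% 10000L)) {
  if (age < 0 || age > 120) stop("age outside [0,120]")
  shape <- cfg@shape
  g <- templateGeometry(shape)
  f <- 1 + cfg@ageBeta * (age - cfg@ageCenter)
  if (f <= 0) stop("degenerate atrophy factor")
  seeds <- (as.integer(subjectSeed) + c(0L, 1L, 2L) * 1000003L) %% 2147483000L
  v <- randomVelocity(shape, cfg@deformSd, cfg@deformSmooth, seeds[1]) +
       atrophyVelocity(shape, g$atlas, g$roiNames, g$roiCenters,
                       cfg@atrophyRois, f)
  vf <- velocityField(v, phantomSpacing)
  fwd <- exponentiate(vf, nSteps = 6L, from = "template", to = "subject")
  inv <- invertDeformation(fwd)          # subject grid -> template coords
  at <- gridCoords(shape) + matrix(inv@disp, ncol = 3)
  geoS <- array(interpNearest(g$geo, at), shape)
  atlasS <- array(interpNearest(g$atlas, at), shape)
  labels <- geoS * (geoS <= 5)
  counts <- tabulate(labels[labels > 0], 5L)
  if (any(counts < 16L))
    stop(sprintf("degenerate phantom: class sizes %s",
                 paste(counts, collapse = ",")))
  lut1 <- c(cfg@classMeansT1, cfg@csfT1)   # codes 1..6
  lut2 <- c(cfg@classMeansT2, cfg@csfT2)
  m1 <- array(cfg@bgT1, shape); m2 <- array(cfg@bgT2, shape)
  nz <- geoS > 0
  m1[nz] <- lut1[geoS[nz]]
  m2[nz] <- lut2[geoS[nz]]
  bias <- generateBiasField(shape, cfg@biasAmplitude, cfg@biasSmooth, seeds[2])
  set.seed(seeds[3])
  nvox <- prod(shape)
  t1 <- m1 * bias@data + stats::rnorm(nvox, 0, cfg@noiseSd[1])
  t2 <- m2 * bias@data + stats::rnorm(nvox, 0, cfg@noiseSd[2])
  t1 <- pmax(t1, 1e-3); t2 <- pmax(t2, 1e-3)
  mask <- maskVolume((labels > 0) + 0, phantomSpacing)
  gm <- array(0, shape); wm <- array(0, shape); csf <- array(0, shape)
  gm[geoS == 3 | geoS == 5] <- 1
  gm[geoS == 2] <- 0.5
  wm[geoS == 4] <- 1
  wm[geoS == 1] <- 0.8
  csf[geoS == 6] <- 1
  csf[geoS == 2] <- 0.5
  new("SubjectGroundTruth", id = id,
      t1 = brainVolume(array(t1, shape), phantomSpacing),
      t2 = brainVolume(array(t2, shape), phantomSpacing),
      tissueMaps = list(gm = brainVolume(gm, phantomSpacing),
                        wm = brainVolume(wm, phantomSpacing),
                        csf = brainVolume(csf, phantomSpacing)),
      brainstemMask = mask,
      trueLabels = labelVolume(labels,
                               c("iron", "shell", "gray_pag", "white",
                                 "gray_nuclei"), phantomSpacing),
      roiAtlas = labelVolume(atlasS, g$roiNames, phantomSpacing),
      age = age, trueDeformation = fwd, seed = as.integer(subjectSeed))
}

#' Generate a synthetic cohort
#'
#' Ages are sampled uniformly on \code{ageRange} and per-subject seeds derived
#' deterministically from the master seed, so the cohort is a pure function
#' of (cfg, n, ageRange, seed).
#'
#' @param cfg a \linkS4class{PhantomConfig}.
#' @param n number of subjects (>= 2).
#' @param ageRange (lo, hi) in years (default 36-100).
#' @param seed master seed (defaults to the config's).
#' @return list of \linkS4class{SubjectGroundTruth}.
#' @export
generateCohort <- function(cfg, n, ageRange = c(36, 100), seed = cfg@seed) {
  if (n < 2L) stop("need at least 2 subjects")
  set.seed(as.integer(seed))
  ages <- stats::runif(n, ageRange[1], ageRange[2])
  seeds <- sample.int(2000000000L, n)
  lapply(seq_len(n), function(i)
    generateSubject(cfg, ages[i], seeds[i], id = sprintf("s%03d", i)))
}

#' Write a cohort to disk
#'
#' Emits per-subject NIfTI volumes (t1, t2, tissue maps, mask, labels, atlas)
#' plus a CSV manifest (subject_id, age, seed) and the configuration as a
#' key=value text file.
#'
#' @param cohort list of \linkS4class{SubjectGroundTruth}.
#' @param dir output directory.
#' @param cfg the \linkS4class{PhantomConfig} used (written alongside).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort) {
    sd <- file.path(dir, s@id)
    if (!dir.exists(sd)) dir.create(sd)
    writeVolume(s@t1, file.path(sd, "t1.nii.gz"))
    writeVolume(s@t2, file.path(sd, "t2.nii.gz"))
    writeVolume(s@tissueMaps$gm, file.path(sd, "gm.nii.gz"))
    writeVolume(s@tissueMaps$wm, file.path(sd, "wm.nii.gz"))
    writeVolume(s@tissueMaps$csf, file.path(sd, "csf.nii.gz"))
    writeVolume(s@brainstemMask, file.path(sd, "brainstem_mask.nii.gz"))
    writeVolume(s@trueLabels, file.path(sd, "true_labels.nii.gz"))
    writeVolume(s@roiAtlas, file.path(sd, "roi_atlas.nii.gz"))
  }
  manifest <- data.frame(subject_id = vapply(cohort, function(s) s@id, ""),
                         age = vapply(cohort, function(s) s@age, 0),
                         seed = vapply(cohort, function(s) s@seed, 0L))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  if (!is.null(cfg)) writePhantomConfig(cfg, file.path(dir, "phantom_config.txt"))
  invisible(path)
}

#' Write / read a phantom configuration as key=value text
#'
#' @param cfg a \linkS4class{PhantomConfig}.
#' @param path text file path.
#' @return \code{path} (write) or a \linkS4class{PhantomConfig} (read).
#' @export
writePhantomConfig <- function(cfg, path) {
  num <- function(x) paste(x, collapse = ",")
  lines <- c(
    paste0("shape=", num(cfg@shape)),
    paste0("class_means_t1=", num(cfg@classMeansT1)),
    paste0("class_means_t2=", num(cfg@classMeansT2)),
    paste0("csf_t1=", cfg@csfT1), paste0("csf_t2=", cfg@csfT2),
    paste0("bg_t1=", cfg@bgT1), paste0("bg_t2=", cfg@bgT2),
    paste0("noise_sd=", num(cfg@noiseSd)),
    paste0("bias_amplitude=", cfg@biasAmplitude),
    paste0("bias_smooth=", cfg@biasSmooth),
    paste0("deform_sd=", cfg@deformSd),
    paste0("deform_smooth=", cfg@deformSmooth),
    paste0("age_beta=", cfg@ageBeta),
    paste0("age_center=", cfg@ageCenter),
    paste0("atrophy_rois=", num(cfg@atrophyRois)),
    paste0("seed=", cfg@seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePhantomConfig
#' @export
readPhantomConfig <- function(path) {
  kv <- utils::read.table(path, sep = "=", col.names = c("k", "v"),
                          stringsAsFactors = FALSE)
  get <- function(k) kv$v[kv$k == k]
  nums <- function(k) as.numeric(strsplit(get(k), ",")[[1]])
  cm <- function(k) stats::setNames(nums(k), c("iron", "shell", "gray_pag",
                                               "white", "gray_nuclei"))
  phantomConfig(shape = as.integer(nums("shape")),
                classMeansT1 = cm("class_means_t1"),
                classMeansT2 = cm("class_means_t2"),
                csfT1 = nums("csf_t1"), csfT2 = nums("csf_t2"),
                bgT1 = nums("bg_t1"), bgT2 = nums("bg_t2"),
                noiseSd = nums("noise_sd"),
                biasAmplitude = nums("bias_amplitude"),
                biasSmooth = nums("bias_smooth"),
                deformSd = nums("deform_sd"),
                deformSmooth = nums("deform_smooth"),
                ageBeta = nums("age_beta"), ageCenter = nums("age_center"),
                atrophyRois = strsplit(get("atrophy_rois"), ",")[[1]],
                seed = as.integer(nums("seed")))
}
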