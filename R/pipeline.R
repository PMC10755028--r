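#' Pipeline configuration
#'
#' Bundles every tunable parameter with its default: reference intensities
#' 100/20, k = 5 clusters, 1000 k-means iterations and 100 replicates,
#' vessel-exclusion percentiles 1/99, tissue-probability threshold 0.9,
#' subject tissue-mask threshold 45, prior evaluation threshold 0.3,
#' reassignment rules 0.75 / 0.20, silhouette cutoff 0.6 with a 10000-voxel
#' subsample, FDR q = 0.05, and the registration schedule.
#'
#' @param ... overrides for any top-level entry (partial lists are merged).
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    refs = referencePair(),
    k = 5L,
    kmeans = list(maxIter = 1000L, replicates = 100L, seed = 1L),
    maskThreshold = 45,
    percentiles = c(low = 1, high = 99),
    tissueProbThreshold = 0.9,
    priorEvalThreshold = 0.3,
    reassign = list(altThreshold = 0.75, margin = 0.20),
    registration = list(levels = c(4L, 2L, 1L), smooth = 2,
                        iters = c(30L, 20L, 10L), nIters = 2L, expSteps = 6L),
    silhouette = list(sampleSize = 10000L, cutoff = 0.6),
    fdrQ = 0.05,
    channels = c("T1", "T2", "RATIO"))
  ov <- list(...)
  for (k in names(ov)) {
    if (is.list(cfg[[k]]) && is.list(ov[[k]]))
      cfg[[k]][names(ov[[k]])] <- ov[[k]]
    else cfg[[k]] <- ov[[k]]
  }
  cfg
}

#' First-pass segmentation of one subject
#'
#' Runs the per-subject half of the pipeline: histogram-mode estimation on
#' high-probability tissue voxels, two-point recalibration of T1 and T2,
#' negative-voxel repair, RATIO computation with extreme-voxel repair,
#' subject tissue-mask extraction, z-scored feature construction, k-means
#' with replicates, optional centroid matching to a reference subject, and
#' binary first-pass cluster maps. Deterministic given the config seed.
#'
#' @param t1,t2 bias-corrected, co-registered \linkS4class{BrainVolume}s.
#' @param tissueMaps list with \code{wm} and \code{csf} probability volumes.
#' @param brainstemMask brainstem/thalamus label \linkS4class{MaskVolume}.
#' @param cfg a \code{\link{pipelineConfig}} list.
#' @param reference optional reference \linkS4class{ClusterModel} for
#'   centroid matching.
#' @param seed k-means seed override.
#' @return list with elements model, binaryMaps, mask, fm, t1cal, t2cal,
#'   ratio, rescale (list of T1/T2 \linkS4class{RescaleParams}).
#' @export
runSubjectFirstpass <- function(t1, t2, tissueMaps, brainstemMask,
                                cfg = pipelineConfig(), reference = NULL,
                                seed = cfg$kmeans$seed) {
  if (is.null(t1)) stop("missing input: t1")
  if (is.null(t2)) stop("missing input: t2")
  if (is.null(tissueMaps$wm) || is.null(tissueMaps$csf))
    stop("missing input: tissue maps (wm, csf)")
  if (is.null(brainstemMask)) stop("missing input: brainstemMask")
  modes1 <- tissueModes(t1, tissueMaps$wm, tissueMaps$csf, "T1",
                        cfg$tissueProbThreshold)
  modes2 <- tissueModes(t2, tissueMaps$wm, tissueMaps$csf, "T2",
                        cfg$tissueProbThreshold)
  p1 <- fitRescale(modes1[["wm"]], modes1[["csf"]], cfg$refs, "T1")
  p2 <- fitRescale(modes2[["wm"]], modes2[["csf"]], cfg$refs, "T2")
  t1cal <- repairNegative(applyRescale(t1, p1), brainstemMask)
  t2cal <- repairNegative(applyRescale(t2, p2), brainstemMask)
  ratio <- computeRatio(t1cal, t2cal, brainstemMask,
                        percentile = cfg$percentiles[["high"]])
  mask <- makeBrainstemTissueMask(t1cal, brainstemMask, cfg$maskThreshold)
  fm <- buildFeatures(t1cal, t2cal, ratio, mask, cfg$channels)
  model <- kmeansFit(fm, cfg$k, cfg$kmeans$maxIter, cfg$kmeans$replicates,
                     seed)
  if (!is.null(reference)) model <- matchClusterLabels(model, reference)
  list(model = model, binaryMaps = toBinaryMaps(model, mask), mask = mask,
       fm = fm, t1cal = t1cal, t2cal = t2cal, ratio = ratio,
       rescale = list(T1 = p1, T2 = p2))
}

## stack a list of MaskVolumes into a (x,y,z,k) numeric array
stackMaps <- function(maps) {
  shape <- dim(maps[[1]]@data)
  out <- array(0, c(shape, length(maps)))
  for (j in seq_along(maps)) out[, , , j] <- maps[[j]]@data
  out
}

## binary maps from an integer label vector on a grid
labelsToMaps <- function(model, mask) toBinaryMaps(model, mask)

#' Run the full pipeline on a cohort
#'
#' First-pass segmentation for every subject (centroid numbering matched to
#' the first subject), groupwise template building on the binary first-pass
#' maps, prior construction and projection into each subject's space,
#' prior-consistency reassignment, probabilistic final segmentation, a second
#' template build on the final probabilistic maps, Jacobian-determinant maps
#' from its template-to-subject deformations, ROI mean extraction with the
#' template-space atlas, and age regression with FDR control.
#'
#' @param cohort list of \linkS4class{SubjectGroundTruth} (or any list whose
#'   elements carry t1, t2, tissueMaps, brainstemMask, age, id slots).
#' @param cfg a \code{\link{pipelineConfig}} list.
#' @param atlas template-space \linkS4class{LabelVolume} of morphometry ROIs
#'   (defaults to the phantom atlas of the cohort's grid).
#' @param verbose print stage progress.
#' @return list with firstpass, priors (\linkS4class{PriorSet}),
#'   projectedPriors, models (reassigned), finals, templates (two
#'   \linkS4class{TemplateSet}s), jacobians, roiMeasurements, ageModels.
#' @export
runCohort <- function(cohort, cfg = pipelineConfig(), atlas = NULL,
                      verbose = FALSE) {
  n <- length(cohort)
  if (n < 2L) stop("need at least 2 subjects")
  say <- function(...) if (verbose) message(sprintf(...))
  say("first-pass segmentation of %d subjects", n)
  fp <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    fp[[i]] <- runSubjectFirstpass(
      s@t1, s@t2, s@tissueMaps, s@brainstemMask, cfg,
      reference = if (i > 1L) fp[[1]]$model else NULL,
      seed = cfg$kmeans$seed + i)
  }
  say("groupwise template on first-pass maps")
  reg <- cfg$registration
  binStacks <- lapply(fp, function(x) stackMaps(x$binaryMaps))
  tpl1 <- buildGroupTemplate(binStacks, nIters = reg$nIters,
                             expSteps = reg$expSteps, levels = reg$levels,
                             smooth = reg$smooth, iters = reg$iters)
  priors <- priorSet(tpl1@template, evalThreshold = cfg$priorEvalThreshold)
  say("projecting priors and reassigning")
  projected <- vector("list", n)
  models <- vector("list", n)
  finals <- vector("list", n)
  for (i in seq_len(n)) {
    projected[[i]] <- projectPriors(priors, tpl1@inverse[[i]])
    models[[i]] <- consistencyReassign(fp[[i]]$model, projected[[i]],
                                       cfg$reassign$altThreshold,
                                       cfg$reassign$margin)
    bm <- toBinaryMaps(models[[i]], fp[[i]]$mask)
    finals[[i]] <- toProbabilistic(bm, projected[[i]], models[[i]])
  }
  say("second template build on probabilistic finals")
  finalStacks <- lapply(finals, function(x) x@maps)
  tpl2 <- buildGroupTemplate(finalStacks, nIters = reg$nIters,
                             expSteps = reg$expSteps, levels = reg$levels,
                             smooth = reg$smooth, iters = reg$iters)
  say("Jacobians and ROI statistics")
  if (is.null(atlas)) atlas <- templateAtlas(dim(cohort[[1]]@t1@data))
  jac <- lapply(tpl2@forward, jacobianDeterminant,
                spacing = cohort[[1]]@t1@spacing)
  meas <- do.call(rbind, lapply(seq_len(n), function(i)
    extractRoiMeans(jac[[i]], atlas, subjectId = cohort[[i]]@id,
                    age = cohort[[i]]@age)))
  models_fit <- NULL
  if (n >= 4L) models_fit <- fitAgeModels(meas, q = cfg$fdrQ)
  else message("fewer than 4 subjects: age regression skipped")
  list(firstpass = fp, priors = priors, projectedPriors = projected,
       models = models, finals = finals, templates = list(tpl1, tpl2),
       jacobians = jac, roiMeasurements = meas, ageModels = models_fit)
}

#' Compare clustering input variants on a common-space cohort
#'
#' Fits the k-means segmentation with each channel subset, builds each
#' variant's probabilistic group average as the voxelwise label frequency
#' across subjects, and reports the three quality indices per subject and
#' variant. Assumes the cohort shares one geometry (deformSd = 0), so priors
#' need no registration; with shape variation, use \code{\link{runCohort}}
#' per variant instead.
#'
#' @param cohort list of \linkS4class{SubjectGroundTruth} in a common space.
#' @param cfg a \code{\link{pipelineConfig}} list.
#' @param variants named list of channel subsets (default: the six studied
#'   combinations).
#' @return data.frame of \code{\link{segQualityReport}} rows.
#' @export
compareVariants <- function(cohort, cfg = pipelineConfig(),
                            variants = list(
                              "T1+T2+RATIO" = c("T1", "T2", "RATIO"),
                              "RATIO" = "RATIO",
                              "T1" = "T1",
                              "T2" = "T2",
                              "RATIO+T2" = c("T2", "RATIO"),
                              "T1+T2" = c("T1", "T2"))) {
  n <- length(cohort)
  rows <- list()
  for (vn in names(variants)) {
    vcfg <- cfg
    vcfg$channels <- variants[[vn]]
    fits <- vector("list", n)
    for (i in seq_len(n)) {
      s <- cohort[[i]]
      fits[[i]] <- runSubjectFirstpass(
        s@t1, s@t2, s@tissueMaps, s@brainstemMask, vcfg,
        reference = if (i > 1L) fits[[1]]$model else NULL,
        seed = vcfg$kmeans$seed + i)
    }
    priors <- buildPriors(lapply(fits, function(x) stackMaps(x$binaryMaps)),
                          evalThreshold = cfg$priorEvalThreshold)
    priors@frame <- "subject"     # common space: template == subject grid
    for (i in seq_len(n))
      rows[[length(rows) + 1L]] <- cbind(
        subject_id = cohort[[i]]@id,
        segQualityReport(vn, fits[[i]]$model, fits[[i]]$fm, priors,
                         sampleSize = cfg$silhouette$sampleSize,
                         seed = cfg$kmeans$seed + i,
                         cutoff = cfg$silhouette$cutoff))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
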