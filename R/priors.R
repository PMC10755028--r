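#' Construct a PriorSet
#'
#' @param maps 4D (x,y,z,k) probability array.
#' @param frame space tag.
#' @param evalThreshold misclassification-index threshold (default 0.3).
#' @return A \linkS4class{PriorSet}.
#' @export
priorSet <- function(maps, frame = "template", evalThreshold = 0.3) {
  new("PriorSet", maps = maps, frame = frame, evalThreshold = evalThreshold)
}

#' @rdname priorSet
#' @param x a PriorSet.
#' @export
priorMaps <- function(x) x@maps

#' Build probabilistic group-average priors
#'
#' Prior of cluster k = voxelwise mean, across subjects, of the warped binary
#' first-pass map of cluster k: the frequency with which a template voxel is
#' assigned to that cluster in the cohort.
#'
#' @param warpedBinaryMaps list of per-subject 4D (x,y,z,5) arrays in
#'   template space (binary maps warped by the groupwise registration, so
#'   values may be fractional in [0,1] after interpolation).
#' @param evalThreshold stored threshold for downstream evaluation.
#' @return A \linkS4class{PriorSet} in template space.
#' @export
buildPriors <- function(warpedBinaryMaps, evalThreshold = 0.3) {
  n <- length(warpedBinaryMaps)
  if (n < 2L) stop("need at least 2 subjects")
  d4 <- dim(warpedBinaryMaps[[1]])
  if (d4[4] != 5L) stop("expected 5 cluster channels, got ", d4[4])
  maps <- Reduce("+", warpedBinaryMaps) / n
  maps[maps < 0] <- 0
  maps[maps > 1] <- 1
  priorSet(maps, frame = "template", evalThreshold = evalThreshold)
}

#' Project template-space priors into a subject's space
#'
#' Warps every prior channel through the subject's inverse deformation
#' (subject grid -> template coordinates) with linear interpolation and
#' clamps to [0,1].
#'
#' @param priors a template-space \linkS4class{PriorSet}.
#' @param inverseDeformation the subject's inverse
#'   \linkS4class{DeformationField} (subject -> template).
#' @return A subject-space \linkS4class{PriorSet}.
#' @export
projectPriors <- function(priors, inverseDeformation) {
  shape <- dim(inverseDeformation@disp)[1:3]
  if (!identical(dim(priors@maps)[1:3], shape)) stop("grids differ")
  k <- dim(priors@maps)[4]
  p <- trilinearPrep(shape,
                     gridCoords(shape) + matrix(inverseDeformation@disp, ncol = 3))
  out <- array(0, dim(priors@maps))
  for (j in seq_len(k))
    out[, , , j] <- array(trilinearApply(priors@maps[, , , j], p), shape)
  out[out < 0] <- 0
  out[out > 1] <- 1
  priorSet(out, frame = "subject", evalThreshold = priors@evalThreshold)
}

#' Prior-consistency reassignment of first-pass labels
#'
#' A voxel's assignment is consistent when its k-means cluster is also the
#' cluster with the highest prior probability at that voxel. Inconsistent
#' voxels are reassigned to the prior-argmax (alternate) cluster when either
#' printed rule fires: (1) the alternate prior probability is >= 0.75, or
#' (2) it exceeds the assigned cluster's prior probability by >= 0.20.
#' Ties in the argmax go to the lower cluster index.
#'
#' @param model a matched \linkS4class{ClusterModel} holding first-pass labels.
#' @param subjectPriors subject-space \linkS4class{PriorSet}.
#' @param altThreshold rule-1 probability threshold (default 0.75).
#' @param margin rule-2 probability margin (default 0.20).
#' @return the model with reassigned labels; the per-rule voxel counts are in
#'   \code{attr(.., "reassignLog")}.
#' @export
consistencyReassign <- function(model, subjectPriors, altThreshold = 0.75,
                                margin = 0.20) {
  stopifnot(altThreshold >= 0, altThreshold <= 1, margin >= 0, margin <= 1)
  k <- model@k
  idx <- model@voxelIndex
  P <- matrix(0, length(idx), k)
  for (j in seq_len(k)) {
    ch <- subjectPriors@maps[, , , j]
    P[, j] <- ch[idx]
  }
  alt <- max.col(P, ties.method = "first")
  pAlt <- P[cbind(seq_along(idx), alt)]
  pOwn <- P[cbind(seq_along(idx), model@labels)]
  inconsistent <- alt != model@labels
  rule1 <- inconsistent & pAlt >= altThreshold
  rule2 <- inconsistent & (pAlt - pOwn) >= margin
  move <- rule1 | rule2
  labels <- model@labels
  labels[move] <- alt[move]
  out <- initialize(model, labels = as.integer(labels))
  attr(out@labels, "reassignLog") <- list(
    n_inconsistent = sum(inconsistent),
    n_rule1 = sum(rule1), n_rule2 = sum(rule2 & !rule1),
    n_reassigned = sum(move))
  out
}

#' Convert binary maps to the probabilistic final segmentation
#'
#' Final probability of cluster k at voxel v is the product
#' binary_k(v) x prior_k(v) x stdDistance(v): the binary membership weighted
#' by the population prior and by the voxel's standardized proximity to its
#' centroid. Hard labels are the argmax over clusters wherever some
#' probability is positive.
#'
#' @param binaryMaps list of 5 \linkS4class{MaskVolume}s (possibly after
#'   reassignment).
#' @param subjectPriors subject-space \linkS4class{PriorSet}.
#' @param model the \linkS4class{ClusterModel} supplying standardized
#'   centroid proximities (and the voxel index).
#' @return A \linkS4class{FinalSegmentation}.
#' @export
toProbabilistic <- function(binaryMaps, subjectPriors, model) {
  k <- length(binaryMaps)
  shape <- dim(binaryMaps[[1]]@data)
  std <- array(0, shape)
  std[model@voxelIndex] <- model@stdDistance
  maps <- array(0, c(shape, k))
  for (j in seq_len(k))
    maps[, , , j] <- binaryMaps[[j]]@data * subjectPriors@maps[, , , j] * std
  flat <- matrix(maps, ncol = k)
  hard <- max.col(flat, ties.method = "first")
  hard[rowSums(flat) <= 0] <- 0L
  hardVol <- labelVolume(array(hard, shape),
                         labelNames = paste0("cluster", seq_len(k)),
                         spacing = binaryMaps[[1]]@spacing,
                         origin = binaryMaps[[1]]@origin,
                         frame = binaryMaps[[1]]@frame)
  log <- attr(model@labels, "reassignLog")
  new("FinalSegmentation", maps = maps, hardLabels = hardVol,
      reassignLog = if (is.null(log)) list() else log)
}

#' Write a final segmentation to disk
#'
#' Emits one NIfTI per cluster probability map, a hard-label NIfTI, and the
#' reassignment log as JSON.
#'
#' @param fseg a \linkS4class{FinalSegmentation}.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
writeFinalSegmentation <- function(fseg, dir, prefix = "final") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- dim(fseg@maps)[4]
  shape <- dim(fseg@maps)[1:3]
  sp <- fseg@hardLabels@spacing
  for (j in seq_len(k))
    writeVolume(brainVolume(array(fseg@maps[, , , j], shape), sp),
                file.path(dir, sprintf("%s_cluster%d.nii.gz", prefix, j)))
  writeVolume(fseg@hardLabels, file.path(dir, paste0(prefix, "_labels.nii.gz")))
  jsonlite::write_json(fseg@reassignLog,
                       file.path(dir, paste0(prefix, "_reassign.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
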