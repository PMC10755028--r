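#' Silhouette coefficients on a seeded subsample
#'
#' s(i) = (b - a) / max(a, b), with a the mean distance of point i to its own
#' cluster's other members and b the smallest mean distance to another
#' cluster, computed exactly within a seeded subsample of
#' min(sampleSize, n) voxels (exact all-voxel silhouettes are quadratic in n).
#' Points whose cluster is a singleton within the subsample score 0.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param labels per-voxel cluster ids (same order as the rows of \code{fm}).
#' @param sampleSize subsample cap (default 10000).
#' @param seed RNG seed for the subsample.
#' @return numeric vector of silhouette coefficients (one per sampled voxel).
#' @export
silhouetteValues <- function(fm, labels, sampleSize = 10000L, seed = 1L) {
  X <- fm@x
  n <- nrow(X)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  set.seed(as.integer(seed))
  sel <- if (n > sampleSize) sort(sample.int(n, sampleSize)) else seq_len(n)
  Xs <- X[sel, , drop = FALSE]
  ls <- labels[sel]
  m <- length(sel)
  D <- as.matrix(stats::dist(Xs))
  clusters <- sort(unique(ls))
  ## mean distance of each point to every cluster
  M <- vapply(clusters, function(cl) rowSums(D[, ls == cl, drop = FALSE]),
              numeric(m))
  sizes <- vapply(clusters, function(cl) sum(ls == cl), integer(1))
  own <- match(ls, clusters)
  s <- numeric(m)
  for (i in seq_len(m)) {
    ni <- sizes[own[i]]
    if (ni <= 1L) { s[i] <- 0; next }
    a <- M[i, own[i]] / (ni - 1L)
    b <- min(M[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Misclassification index
#'
#' For each cluster k, the fraction of voxels assigned to k whose projected
#' prior probability for k falls below the threshold (default 0.3); the index
#' is the unweighted mean over the five clusters (empty clusters skipped).
#' Low values indicate good clustering.
#'
#' @param model a \linkS4class{ClusterModel} (labels in subject space).
#' @param subjectPriors subject-space \linkS4class{PriorSet}.
#' @param threshold prior probability cutoff; defaults to the PriorSet's
#'   \code{evalThreshold}.
#' @return fraction in [0,1].
#' @export
misclassificationIndex <- function(model, subjectPriors, threshold = NULL) {
  if (is.null(threshold)) threshold <- subjectPriors@evalThreshold
  fr <- perClusterMisclassified(model, subjectPriors, threshold)$fraction
  mean(fr, na.rm = TRUE)
}

## per-cluster misclassified-voxel bookkeeping shared by the two indices
perClusterMisclassified <- function(model, subjectPriors, threshold) {
  k <- model@k
  idx <- model@voxelIndex
  fraction <- rep(NA_real_, k)
  mis <- vector("list", k)
  for (j in seq_len(k)) {
    sel <- model@labels == j
    if (!any(sel)) next
    pj <- subjectPriors@maps[, , , j][idx[sel]]
    bad <- pj < threshold
    fraction[j] <- mean(bad)
    mis[[j]] <- which(sel)[bad]
  }
  list(fraction = fraction, misclassified = mis)
}

#' Misclassification distance
#'
#' Mean standardized centroid proximity of the misclassified voxels (as
#' defined by \code{\link{misclassificationIndex}}) per cluster, averaged over
#' clusters; clusters without misclassified voxels are skipped. When no
#' cluster has misclassified voxels the value is undefined and 0 is returned
#' with a warning.
#'
#' @inheritParams misclassificationIndex
#' @return mean proximity in [0,1].
#' @export
misclassificationDistance <- function(model, subjectPriors, threshold = NULL) {
  if (is.null(threshold)) threshold <- subjectPriors@evalThreshold
  mis <- perClusterMisclassified(model, subjectPriors, threshold)$misclassified
  means <- vapply(mis, function(rows)
    if (is.null(rows) || length(rows) == 0L) NA_real_
    else mean(model@stdDistance[rows]), numeric(1))
  if (all(is.na(means))) {
    warning("no misclassified voxels; misclassification distance undefined")
    return(0)
  }
  mean(means, na.rm = TRUE)
}

#' Subthreshold silhouette index
#'
#' Fraction of sampled voxels whose silhouette coefficient falls below the
#' cutoff (default 0.6). A clustering that successfully downgrades
#' noise-misassigned voxels has a high index.
#'
#' @param silhouettes output of \code{\link{silhouetteValues}}.
#' @param cutoff silhouette cutoff (default 0.6).
#' @return fraction in [0,1].
#' @export
subthresholdSilhouetteIndex <- function(silhouettes, cutoff = 0.6) {
  if (length(silhouettes) == 0L) stop("empty silhouette vector")
  mean(silhouettes < cutoff)
}

#' Agreement with phantom ground truth
#'
#' Adjusted Rand index between the clustering and the true labels over the
#' in-mask voxels (permutation invariant), plus per-class Dice after optimal
#' one-to-one class matching (the permutation maximizing total Dice).
#'
#' @param labels integer vector of cluster assignments.
#' @param trueLabels integer vector of ground-truth classes (same voxels,
#'   same order).
#' @return list with \code{ari}, \code{dice} (named per matched true class)
#'   and \code{matching} (cluster id assigned to each true class).
#' @export
groundTruthAgreement <- function(labels, trueLabels) {
  if (length(labels) != length(trueLabels))
    stop("label vectors differ in length")
  ari <- mclust::adjustedRandIndex(labels, trueLabels)
  tcl <- sort(unique(trueLabels))
  pcl <- sort(unique(labels))
  k <- max(length(tcl), length(pcl))
  diceM <- matrix(0, k, k)
  for (i in seq_along(tcl)) for (j in seq_along(pcl)) {
    a <- trueLabels == tcl[i]
    b <- labels == pcl[j]
    diceM[i, j] <- 2 * sum(a & b) / (sum(a) + sum(b))
  }
  perms <- permutations(k)
  tot <- vapply(seq_len(nrow(perms)),
                function(r) sum(diceM[cbind(seq_len(k), perms[r, ])]),
                numeric(1))
  sigma <- perms[which.max(tot), ]
  dice <- diceM[cbind(seq_along(tcl), sigma[seq_along(tcl)])]
  names(dice) <- paste0("class", tcl)
  list(ari = ari, dice = dice,
       matching = stats::setNames(pcl[pmin(sigma[seq_along(tcl)], length(pcl))],
                                  paste0("class", tcl)))
}

#' Segmentation-quality report for one clustering variant
#'
#' Bundles the three quality indices for a fitted model evaluated against
#' subject-space priors.
#'
#' @param variant channel-set tag (e.g. "T1+T2+RATIO").
#' @param model \linkS4class{ClusterModel}.
#' @param fm the \linkS4class{FeatureMatrix} the model was fitted on.
#' @param subjectPriors subject-space \linkS4class{PriorSet}.
#' @param sampleSize,seed silhouette subsampling controls.
#' @param cutoff silhouette cutoff.
#' @return one-row data.frame.
#' @export
segQualityReport <- function(variant, model, fm, subjectPriors,
                             sampleSize = 10000L, seed = 1L, cutoff = 0.6) {
  s <- silhouetteValues(fm, model@labels, sampleSize, seed)
  data.frame(
    variant = variant,
    misclassification_index = misclassificationIndex(model, subjectPriors),
    misclassification_distance =
      suppressWarnings(misclassificationDistance(model, subjectPriors)),
    subthreshold_silhouette_index = subthresholdSilhouetteIndex(s, cutoff),
    n_voxels = length(model@labels),
    seed = seed,
    stringsAsFactors = FALSE)
}
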