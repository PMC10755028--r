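#' Subject-specific brainstem tissue mask
#'
#' Intersects the brainstem/thalamus label with a threshold on the
#' recalibrated T1 (removing CSF, whose recalibrated intensity sits at the
#' lower reference), then keeps the largest 6-connected component.
#'
#' @param t1cal recalibrated T1 \linkS4class{BrainVolume}.
#' @param brainstemLabel \linkS4class{MaskVolume} of the brainstem region.
#' @param threshold intensity cutoff (default 45, between the CSF target 20
#'   and tissue intensities).
#' @return A \linkS4class{MaskVolume}.
#' @export
makeBrainstemTissueMask <- function(t1cal, brainstemLabel, threshold = 45) {
  if (!identical(dim(t1cal@data), dim(brainstemLabel@data)))
    stop("grids differ")
  m <- (brainstemLabel@data != 0) & (t1cal@data > threshold)
  if (!any(m)) stop("empty tissue mask: threshold above all in-label voxels")
  keep <- largestComponent(which(m), dim(m))
  out <- array(0, dim(m))
  out[keep] <- 1
  maskVolume(out, t1cal@spacing, t1cal@origin, t1cal@frame)
}

## largest 6-connected component of a voxel index set (BFS flood fill)
largestComponent <- function(index, shape) {
  inset <- logical(prod(shape))
  inset[index] <- TRUE
  seen <- logical(prod(shape))
  best <- integer(0)
  for (s in index) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0L) {
      nb <- neighborIndexMatrix(frontier, shape)
      nb <- nb[!is.na(nb)]
      nb <- unique(nb[inset[nb] & !seen[nb]])
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
    if (length(best) > sum(inset) - length(best)) break  # no larger one left
  }
  sort(best)
}

#' Construct a FeatureMatrix directly
#'
#' Wraps a plain numeric matrix (rows = observations, columns = channels) for
#' use with \code{\link{kmeansFit}} and the evaluation utilities; no
#' z-scoring is applied (see \code{\link{buildFeatures}} for the standard
#' in-mask z-scored construction).
#'
#' @param x numeric matrix.
#' @param channels column names (default V1..Vp).
#' @param voxelIndex optional linear grid indices per row.
#' @param dim optional grid dims.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
featureMatrix <- function(x, channels = NULL, voxelIndex = NULL, dim = NULL) {
  x <- as.matrix(x)
  if (is.null(channels)) channels <- paste0("V", seq_len(ncol(x)))
  if (is.null(voxelIndex)) voxelIndex <- seq_len(nrow(x))
  if (is.null(dim)) dim <- c(nrow(x), 1L, 1L)
  new("FeatureMatrix", x = x, channels = channels,
      voxelIndex = as.integer(voxelIndex), dim = as.integer(dim))
}

#' Build the z-scored multichannel feature matrix
#'
#' Extracts in-mask intensities of the selected channels (subset of
#' \code{"T1"}, \code{"T2"}, \code{"RATIO"}) in canonical raster order and
#' converts each channel to z-scores over the in-mask voxels. Z-scoring is
#' per subject and in-mask, which makes the features invariant to any global
#' affine intensity scaling of a channel.
#'
#' @param t1cal,t2cal,ratio recalibrated channel volumes (any not in
#'   \code{channels} may be NULL).
#' @param mask analysis \linkS4class{MaskVolume}.
#' @param channels character subset of c("T1","T2","RATIO").
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatures <- function(t1cal, t2cal, ratio, mask,
                          channels = c("T1", "T2", "RATIO")) {
  stopifnot(length(channels) >= 1L,
            all(channels %in% c("T1", "T2", "RATIO")))
  vols <- list(T1 = t1cal, T2 = t2cal, RATIO = ratio)
  idx <- which(mask@data != 0)
  if (length(idx) == 0L) stop("empty mask")
  cols <- lapply(channels, function(ch) {
    v <- vols[[ch]]
    if (is.null(v)) stop("channel ", ch, " requested but volume is NULL")
    if (!identical(dim(v@data), dim(mask@data))) stop("grids differ")
    x <- v@data[idx]
    s <- stats::sd(x)
    if (s == 0) stop("zero-variance channel: ", ch)
    (x - mean(x)) / s
  })
  new("FeatureMatrix", x = do.call(cbind, cols), channels = channels,
      voxelIndex = idx, dim = dim(mask@data))
}

#' k-means clustering with seeded replicates
#'
#' Lloyd iterations minimizing within-cluster squared Euclidean distance,
#' restarted from \code{replicates} k-means++ initializations; the run with
#' the lowest objective wins. An emptied cluster is re-seeded at the point
#' farthest from its centroid. Deterministic given \code{seed}.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param k number of clusters (default 5).
#' @param maxIter Lloyd iteration cap per replicate (default 1000).
#' @param replicates number of seeded restarts (default 100).
#' @param seed RNG seed.
#' @return A \linkS4class{ClusterModel} (with standardized distances filled).
#' @export
kmeansFit <- function(fm, k = 5L, maxIter = 1000L, replicates = 100L,
                      seed = 1L) {
  X <- fm@x
  n <- nrow(X)
  k <- as.integer(k)
  if (n < k) stop(sprintf("fewer rows (%d) than clusters (%d)", n, k))
  xsq <- rowSums(X^2)
  best <- NULL
  set.seed(as.integer(seed))
  for (rep_i in seq_len(replicates)) {
    C <- kppInit(X, k, xsq)
    labels <- integer(n)
    for (it in seq_len(maxIter)) {
      D <- sqDistToCentroids(X, C, xsq)
      newLabels <- max.col(-D, ties.method = "first")
      ## re-seed empty clusters at the globally farthest point
      for (j in which(tabulate(newLabels, k) == 0L)) {
        d2own <- D[cbind(seq_len(n), newLabels)]
        far <- which.max(d2own)
        C[j, ] <- X[far, ]
        D <- sqDistToCentroids(X, C, xsq)
        newLabels <- max.col(-D, ties.method = "first")
      }
      if (identical(newLabels, labels)) break
      labels <- newLabels
      for (j in seq_len(k))
        C[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    D <- sqDistToCentroids(X, C, xsq)
    labels <- max.col(-D, ties.method = "first")
    for (j in seq_len(k))
      C[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    D <- sqDistToCentroids(X, C, xsq)
    sqd <- pmax(D[cbind(seq_len(n), labels)], 0)
    obj <- sum(sqd)
    if (is.null(best) || obj < best$obj)
      best <- list(C = C, labels = labels, sqd = sqd, obj = obj)
  }
  model <- new("ClusterModel", k = k, centroids = best$C,
               labels = as.integer(best$labels), sqDistances = best$sqd,
               stdDistance = numeric(0), objective = best$obj,
               seed = as.integer(seed), channels = fm@channels,
               voxelIndex = fm@voxelIndex, dim = fm@dim)
  standardizeDistances(model)
}

## k-means++ seeding
kppInit <- function(X, k, xsq) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- sqDistToCentroids(X, X[centers[1], , drop = FALSE], xsq)[, 1]
  for (j in 2:k) {
    p <- pmax(d2, 0)
    if (sum(p) <= 0) p <- rep(1, n)
    centers[j] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, sqDistToCentroids(X, X[centers[j], , drop = FALSE], xsq)[, 1])
  }
  X[centers, , drop = FALSE]
}

## n x k matrix of squared Euclidean distances
sqDistToCentroids <- function(X, C, xsq = rowSums(X^2)) {
  D <- matrix(xsq, nrow(X), nrow(C)) - 2 * X %*% t(C)
  sweep(D, 2L, rowSums(C^2), "+")
}

#' Standardize centroid distances to [0,1] proximities
#'
#' Within each cluster, root distances are min-max inverted so the voxel
#' closest to the centroid scores 1 and the farthest 0. Singleton or
#' zero-spread clusters score 1 by convention.
#'
#' @param model a fitted \linkS4class{ClusterModel}.
#' @return the model with \code{stdDistance} filled.
#' @export
standardizeDistances <- function(model) {
  d <- sqrt(model@sqDistances)
  std <- numeric(length(d))
  for (j in seq_len(model@k)) {
    sel <- model@labels == j
    if (!any(sel)) next
    dj <- d[sel]
    rng <- max(dj) - min(dj)
    std[sel] <- if (rng <= 0) 1 else (max(dj) - dj) / rng
  }
  initialize(model, stdDistance = std)
}

#' Match cluster numbering to a reference subject
#'
#' Relabels the model's clusters by the permutation that minimizes the total
#' Euclidean distance between matched centroid pairs (exact optimal
#' assignment by enumeration; k! = 120 permutations at k = 5). Ensures a
#' consistent cluster numbering across subjects.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param reference the reference subject's \linkS4class{ClusterModel}.
#' @return the relabeled \linkS4class{ClusterModel} with an attribute-free
#'   permutation retrievable by comparing centroids.
#' @export
matchClusterLabels <- function(model, reference) {
  if (model@k != reference@k) stop("cluster counts differ")
  if (!identical(model@channels, reference@channels))
    stop("channel sets differ")
  k <- model@k
  cost <- matrix(0, k, k)  # cost[i, j] = dist(model centroid i, ref centroid j)
  for (i in seq_len(k)) for (j in seq_len(k))
    cost[i, j] <- sqrt(sum((model@centroids[i, ] - reference@centroids[j, ])^2))
  perms <- permutations(k)
  tot <- vapply(seq_len(nrow(perms)),
                function(r) sum(cost[cbind(seq_len(k), perms[r, ])]),
                numeric(1))
  sigma <- perms[which.min(tot), ]        # model cluster i -> new label sigma[i]
  inv <- order(sigma)                     # new label j came from old cluster inv[j]
  initialize(model,
             centroids = model@centroids[inv, , drop = FALSE],
             labels = as.integer(sigma[model@labels]))
}

## all permutations of 1..n (n <= 8), in lexicographic order
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[r + seq_len(nrow(sub)), ] <- cbind(first, block)
    r <- r + nrow(sub)
  }
  out
}

#' First-pass binary cluster maps
#'
#' One binary volume per cluster; the maps are voxelwise disjoint and their
#' union equals the analysis mask. Empty clusters yield all-zero maps.
#'
#' @param model a matched \linkS4class{ClusterModel}.
#' @param mask the analysis \linkS4class{MaskVolume} the model was fitted on.
#' @return list of k \linkS4class{MaskVolume}s.
#' @export
toBinaryMaps <- function(model, mask) {
  maps <- vector("list", model@k)
  for (j in seq_len(model@k)) {
    m <- array(0, model@dim)
    m[model@voxelIndex[model@labels == j]] <- 1
    if (sum(m) == 0) message("cluster ", j, " is empty")
    maps[[j]] <- maskVolume(m, mask@spacing, mask@origin, mask@frame)
  }
  maps
}
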