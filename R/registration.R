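#' Construct a VelocityField
#'
#' @param v 4D (x,y,z,3) array of displacement rates in voxel units.
#' @param spacing voxel spacing in mm.
#' @return A \linkS4class{VelocityField}.
#' @export
velocityField <- function(v, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VelocityField", v = v, spacing = as.numeric(spacing))
}

## displacement-field composition: (a o b)(x) = x + b(x) + a(x + b(x)),
## i.e. returned disp(x) = b(x) + a(x + b(x)); a, b are (x,y,z,3) arrays
composeDisp <- function(a, b, coords = gridCoords(dim(a)[1:3])) {
  shape <- dim(a)[1:3]
  n <- prod(shape)
  bmat <- matrix(b, n, 3)
  p <- trilinearPrep(shape, coords + bmat)
  out <- bmat
  dim(a) <- c(n, 3)
  for (c3 in 1:3)
    out[, c3] <- out[, c3] + trilinearApply(a[, c3], p)
  array(out, c(shape, 3L))
}

## scaling-and-squaring exponentiation of a velocity array -> disp array
expDisp <- function(v, nSteps = 6L) {
  disp <- v / 2^nSteps
  coords <- gridCoords(dim(v)[1:3])
  for (s in seq_len(nSteps)) disp <- composeDisp(disp, disp, coords)
  disp
}

#' Exponentiate a stationary velocity field
#'
#' Scaling-and-squaring integration: the velocity is divided by 2^nSteps and
#' the resulting small displacement composed with itself nSteps times,
#' yielding a diffeomorphic deformation. exp(0) is the identity and
#' exp(-v) is the exact group inverse of exp(v).
#'
#' @param v a \linkS4class{VelocityField}.
#' @param nSteps squaring steps (>= 4; default 6).
#' @param from,to frame tags of the resulting field.
#' @return A \linkS4class{DeformationField} retaining \code{v} so that
#'   \code{\link{invertDeformation}} is exact.
#' @export
exponentiate <- function(v, nSteps = 6L, from = "template", to = "subject") {
  stopifnot(nSteps >= 4L)
  if (any(!is.finite(v@v))) stop("non-finite velocity")
  new("DeformationField", disp = expDisp(v@v, nSteps), from = from, to = to,
      velocity = v)
}

#' Invert a deformation field
#'
#' For fields produced by \code{\link{exponentiate}} the stored velocity is
#' negated and re-exponentiated (exact group inverse). Otherwise a
#' fixed-point iteration w(x) = -disp(x + w(x)) is used.
#'
#' @param d a \linkS4class{DeformationField}.
#' @param nSteps squaring steps for the velocity route.
#' @param maxIter fixed-point iterations for the numeric route.
#' @return the inverse \linkS4class{DeformationField}.
#' @export
invertDeformation <- function(d, nSteps = 6L, maxIter = 30L) {
  if (!is.null(d@velocity)) {
    vneg <- velocityField(-d@velocity@v, d@velocity@spacing)
    return(exponentiate(vneg, nSteps, from = d@to, to = d@from))
  }
  jac <- jacobianDeterminantArray(d@disp)
  if (mean(jac <= 0) > 0.01)
    stop(sprintf("field not invertible: %.1f%% non-positive Jacobian",
                 100 * mean(jac <= 0)))
  shape <- dim(d@disp)[1:3]
  coords <- gridCoords(shape)
  w <- array(0, dim(d@disp))
  for (it in seq_len(maxIter)) {
    wmat <- matrix(w, ncol = 3)
    at <- coords + wmat
    neww <- wmat
    for (c3 in 1:3)
      neww[, c3] <- -interpTrilinear(array(d@disp[, , , c3], shape), at)
    delta <- max(abs(neww - wmat))
    w <- array(neww, dim(d@disp))
    if (delta < 1e-4) break
  }
  new("DeformationField", disp = w, from = d@to, to = d@from, velocity = NULL)
}

## compose two DeformationFields: result(x) = a(b(x)) as displacement field
composeDeformations <- function(a, b) {
  new("DeformationField", disp = composeDisp(a@disp, b@disp),
      from = b@from, to = a@to, velocity = NULL)
}

#' Warp a volume through a deformation field
#'
#' Pull-back resampling: output voxel x takes the input volume's value at
#' x + disp(x). Linear interpolation keeps probability maps within [0,1]
#' (convex combination); nearest-neighbor is used for label volumes.
#'
#' @param vol a \linkS4class{BrainVolume} (or subclass) in the field's
#'   \code{to} space.
#' @param d a \linkS4class{DeformationField} living on the output grid.
#' @param interpolation "linear" or "nearest".
#' @return the warped volume (same class as the input for labels/masks).
#' @export
warpVolume <- function(vol, d, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  shape <- dim(d@disp)[1:3]
  if (!identical(dim(vol@data), shape)) stop("grids differ")
  at <- gridCoords(shape) + matrix(d@disp, ncol = 3)
  vals <- if (interpolation == "linear") interpTrilinear(vol@data, at)
          else interpNearest(vol@data, at)
  out <- array(vals, shape)
  if (is(vol, "LabelVolume"))
    labelVolume(out, vol@labelNames, vol@spacing, vol@origin, d@from)
  else if (is(vol, "MaskVolume"))
    maskVolume(out >= 0.5, vol@spacing, vol@origin, d@from)
  else brainVolume(out, vol@spacing, vol@origin, d@from)
}

## one-axis partial derivative by central differences (one-sided at edges)
gradAxis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n == 1L) return(array(0, d))
  idxPlus <- pmin(seq_len(n) + 1L, n)
  idxMinus <- pmax(seq_len(n) - 1L, 1L)
  denom <- idxPlus - idxMinus
  if (axis == 1L) {
    out <- (arr[idxPlus, , , drop = FALSE] - arr[idxMinus, , , drop = FALSE]) /
      array(denom, d)
  } else if (axis == 2L) {
    out <- (arr[, idxPlus, , drop = FALSE] - arr[, idxMinus, , drop = FALSE]) /
      array(rep(denom, each = d[1]), d)
  } else {
    out <- (arr[, , idxPlus, drop = FALSE] - arr[, , idxMinus, drop = FALSE]) /
      array(rep(denom, each = d[1] * d[2]), d)
  }
  out
}

## Jacobian determinant of x + disp(x) on a plain disp array
jacobianDeterminantArray <- function(disp) {
  shape <- dim(disp)[1:3]
  J <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3) {
    g <- gradAxis(array(disp[, , , i], shape), j)
    if (i == j) g <- g + 1
    J[[(i - 1) * 3 + j]] <- g
  }
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
  J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
  J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

#' Jacobian determinant map of a deformation
#'
#' Voxelwise determinant of the finite-difference Jacobian of the map
#' x + disp(x) (central differences in the interior, one-sided at the
#' boundary). With the template -> subject convention, an ROI mean below 1
#' means the subject is locally smaller than the template (atrophy).
#'
#' @param d a \linkS4class{DeformationField} (template -> subject).
#' @param spacing voxel spacing attached to the output volume.
#' @return A \linkS4class{BrainVolume} of determinants (identity -> 1;
#'   negative values are reported as-is, never clamped).
#' @export
jacobianDeterminant <- function(d, spacing = c(1, 1, 1)) {
  brainVolume(jacobianDeterminantArray(d@disp), spacing, frame = d@from)
}

#' Pairwise diffeomorphic registration (multichannel demons)
#'
#' Estimates a stationary velocity field aligning the moving multichannel
#' image to the fixed one by symmetric-forces-free SSD demons: at each
#' iteration the moving channels are warped through exp(v), a demons update
#' field is computed from the channel-summed intensity differences and the
#' (precomputed) fixed-image gradients, added to v with a step size, and v is
#' smoothed (Gaussian, \code{smooth} voxels). Runs coarse-to-fine over \code{levels}
#' (downsampling factors). The SSD objective is tracked per level; an
#' iteration that raises SSD by more than 1\% is rolled back and the level
#' stopped, and a rise above 10\% aborts with diagnostics.
#'
#' @param moving,fixed 4D (x,y,z,channel) arrays with comparable intensities
#'   (e.g. probabilistic cluster maps).
#' @param levels integer downsampling factors, coarse to fine (default 4,2,1).
#' @param smooth Gaussian smoothing of the velocity per iteration, in voxels
#'   of the current level (default 2).
#' @param iters iterations per level (recycled; default 30, 20, 10).
#' @param expSteps scaling-and-squaring steps (default 4 during optimization).
#' @param stepSize demons update step (default 1.5).
#' @param v0 optional warm-start \linkS4class{VelocityField}.
#' @param onDiverge "stop" aborts with diagnostics when SSD rises by more
#'   than 10\%; "rollback" (used inside template building, where a changed
#'   fixed image can transiently raise the warm-started objective) restores
#'   the previous velocity and ends the level.
#' @return A \linkS4class{VelocityField} with an \code{ssd} attribute holding
#'   the per-iteration objective trace.
#' @export
registerPair <- function(moving, fixed, levels = c(4L, 2L, 1L), smooth = 2,
                         iters = c(30L, 20L, 10L), expSteps = 4L,
                         stepSize = 1.5, v0 = NULL,
                         onDiverge = c("stop", "rollback")) {
  onDiverge <- match.arg(onDiverge)
  if (!identical(dim(moving), dim(fixed))) stop("grids differ")
  if (length(dim(moving)) == 3L) {
    dim(moving) <- c(dim(moving), 1L)
    dim(fixed) <- c(dim(fixed), 1L)
  }
  shape <- dim(moving)[1:3]
  nch <- dim(moving)[4]
  iters <- rep(iters, length.out = length(levels))
  v <- NULL
  trace <- numeric(0)
  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    mv <- array(0, c(if (f > 1) dim(downsampleArray(moving[, , , 1], f)) else shape, nch))
    fx <- mv
    for (c4 in seq_len(nch)) {
      mv[, , , c4] <- if (f > 1) downsampleArray(moving[, , , c4], f) else moving[, , , c4]
      fx[, , , c4] <- if (f > 1) downsampleArray(fixed[, , , c4], f) else fixed[, , , c4]
    }
    lshape <- dim(mv)[1:3]
    if (is.null(v)) {
      if (!is.null(v0)) {
        v <- array(0, c(lshape, 3L))
        for (c3 in 1:3)
          v[, , , c3] <- downsampleArray(array(v0@v[, , , c3], shape), f) / f
      } else v <- array(0, c(lshape, 3L))
    } else {
      prevShape <- dim(v)[1:3]
      scale <- lshape[1] / prevShape[1]
      vnew <- array(0, c(lshape, 3L))
      for (c3 in 1:3)
        vnew[, , , c3] <- upsampleArray(array(v[, , , c3], prevShape),
                                        lshape, 1 / scale) * scale
      v <- vnew
    }
    coords <- gridCoords(lshape)
    nvox <- prod(lshape)
    ## fixed-image gradients are constant across iterations: precompute
    G <- vector("list", nch)
    for (c4 in seq_len(nch)) {
      fc <- array(fx[, , , c4], lshape)
      G[[c4]] <- cbind(as.numeric(gradAxis(fc, 1L)),
                       as.numeric(gradAxis(fc, 2L)),
                       as.numeric(gradAxis(fc, 3L)))
    }
    prevSSD <- Inf
    vPrev <- v
    for (it in seq_len(iters[li])) {
      disp <- expDisp(v, expSteps)
      p <- trilinearPrep(lshape, coords + matrix(disp, ncol = 3))
      num <- matrix(0, nvox, 3)
      den <- numeric(nvox)
      ssd <- 0
      for (c4 in seq_len(nch)) {
        w <- trilinearApply(mv[, , , c4], p)
        diffc <- w - as.numeric(fx[, , , c4])
        ssd <- ssd + sum(diffc^2)
        g <- G[[c4]]
        num <- num - diffc * g
        den <- den + g[, 1]^2 + g[, 2]^2 + g[, 3]^2 + diffc^2
      }
      trace <- c(trace, ssd / nvox)
      if (ssd > prevSSD * 1.10 && onDiverge == "stop")
        stop(sprintf(
          "registration diverged at level /%d iteration %d: SSD %.4g -> %.4g",
          f, it, prevSSD, ssd))
      if (ssd > prevSSD * 1.01) { v <- vPrev; break }
      vPrev <- v
      prevSSD <- ssd
      den[den < 1e-9] <- 1e-9
      u <- array(num / den * stepSize, c(lshape, 3L))
      for (c3 in 1:3)
        v[, , , c3] <- smoothArray3D(v[, , , c3] + u[, , , c3], smooth)
    }
  }
  out <- velocityField(v)
  attr(out@v, "ssd") <- trace
  out
}

#' Groupwise template building
#'
#' Iterates between registering every subject's multichannel cluster maps to
#' the current template and averaging the warped maps into a new template,
#' starting from the voxelwise average (the simplified stand-in for
#' groupwise diffeomorphic template construction). Per-subject forward
#' (template -> subject) and inverse deformations are retained; the forward
#' fields are the ones whose Jacobian determinants feed the morphometry.
#'
#' @param subjectMaps list of 4D (x,y,z,k) arrays, one per subject, on one
#'   grid (subject space).
#' @param nIters outer iterations (default 3).
#' @param expSteps squaring steps for the stored deformations (default 6).
#' @param ... passed to \code{\link{registerPair}}.
#' @return A \linkS4class{TemplateSet}.
#' @export
buildGroupTemplate <- function(subjectMaps, nIters = 3L, expSteps = 6L, ...) {
  n <- length(subjectMaps)
  if (n < 2L) stop("need at least 2 subjects")
  d4 <- dim(subjectMaps[[1]])
  for (s in subjectMaps) if (!identical(dim(s), d4)) stop("grids differ")
  template <- Reduce("+", subjectMaps) / n
  velocities <- vector("list", n)
  ssdTrace <- numeric(0)
  for (it in seq_len(nIters)) {
    warpedSum <- array(0, d4)
    ssd <- 0
    for (s in seq_len(n)) {
      v <- registerPair(moving = subjectMaps[[s]], fixed = template,
                        v0 = velocities[[s]], onDiverge = "rollback", ...)
      velocities[[s]] <- v
      disp <- expDisp(v@v, expSteps)
      p <- trilinearPrep(d4[1:3], gridCoords(d4[1:3]) + matrix(disp, ncol = 3))
      for (c4 in seq_len(d4[4])) {
        w <- array(trilinearApply(subjectMaps[[s]][, , , c4], p), d4[1:3])
        warpedSum[, , , c4] <- warpedSum[, , , c4] + w
        ssd <- ssd + sum((w - template[, , , c4])^2)
      }
    }
    ssdTrace <- c(ssdTrace, ssd / n / prod(d4[1:3]))
    template <- warpedSum / n
    template[template < 0] <- 0
    template[template > 1] <- 1
  }
  forward <- lapply(velocities, exponentiate, nSteps = expSteps,
                    from = "template", to = "subject")
  inverse <- lapply(forward, invertDeformation, nSteps = expSteps)
  new("TemplateSet", template = template, forward = forward,
      inverse = inverse, ssdTrace = ssdTrace, nIters = as.integer(nIters))
}
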