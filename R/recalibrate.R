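#' Fixed reference intensities for two-point recalibration
#'
#' The recalibration maps each subject's white-matter and CSF histogram modes
#' to fixed, experimentally determined targets: ref1 = 100 (T1 white matter /
#' T2 CSF) and ref2 = 20 (T1 CSF / T2 white matter). Standardizing both
#' contrasts this way makes the T1/T2 ratio comparable across subjects.
#'
#' @param ref1 upper reference intensity (default 100).
#' @param ref2 lower reference intensity (default 20).
#' @return named numeric(2).
#' @export
referencePair <- function(ref1 = 100, ref2 = 20) {
  stopifnot(ref1 > 0, ref2 > 0, ref1 != ref2)
  c(ref1 = ref1, ref2 = ref2)
}

#' Histogram mode of an intensity sample
#'
#' Mode = center of the most populated bin of a fixed 256-bin histogram over
#' the retained range, after percentile exclusion of vessel-like outliers
#' (below the 1st percentile for T2, above the 99th for T1). Ties are broken
#' toward the lower bin center.
#'
#' @param values numeric intensity vector.
#' @param excludeLow drop values below this percentile (0 = keep all).
#' @param excludeHigh drop values above this percentile (100 = keep all).
#' @param nBins number of histogram bins (default 256).
#' @return the mode intensity; if all retained values are identical, that
#'   value is returned with a warning.
#' @export
histogramMode <- function(values, excludeLow = 0, excludeHigh = 100,
                          nBins = 256L) {
  stopifnot(excludeLow >= 0, excludeHigh <= 100, excludeLow < excludeHigh)
  lo <- if (excludeLow > 0)
    stats::quantile(values, excludeLow / 100, names = FALSE) else -Inf
  hi <- if (excludeHigh < 100)
    stats::quantile(values, excludeHigh / 100, names = FALSE) else Inf
  v <- values[values >= lo & values <= hi]
  if (length(v) < 50L)
    stop(sprintf("too few values after exclusion (%d < 50)", length(v)))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("all values identical after exclusion; returning that value")
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nBins)
  b <- which.max(counts)   # which.max takes the first (lowest) maximal bin
  (breaks[b] + breaks[b + 1L]) / 2
}

#' Fit two-point linear recalibration parameters
#'
#' Computes the unique affine map \code{out = in * fact - shift} that sends
#' the white-matter and CSF histogram modes to the reference targets:
#' for T1, wm -> ref1 and csf -> ref2; for T2 (where CSF is bright and white
#' matter dark) wm -> ref2 and csf -> ref1. The scale factor equals
#' \code{|ref1 - ref2| / |wmMode - csfMode|}.
#'
#' @param wmMode,csfMode histogram modes from high-probability (>= 0.9)
#'   white-matter and CSF voxels.
#' @param refs reference pair from \code{\link{referencePair}}.
#' @param kind "T1" or "T2".
#' @return A \linkS4class{RescaleParams}.
#' @export
fitRescale <- function(wmMode, csfMode, refs = referencePair(), kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  if (wmMode == csfMode) stop("white-matter and CSF modes are equal")
  if (kind == "T1" && wmMode <= csfMode)
    warning("T1 white-matter mode not above CSF mode; check inputs")
  if (kind == "T2" && csfMode <= wmMode)
    warning("T2 CSF mode not above white-matter mode; check inputs")
  targets <- if (kind == "T1") c(refs[["ref1"]], refs[["ref2"]])
             else c(refs[["ref2"]], refs[["ref1"]])
  fact <- abs(refs[["ref1"]] - refs[["ref2"]]) / abs(wmMode - csfMode)
  ## solve wm*fact - shift = target_wm (consistent with csf by construction
  ## when the orientation warnings above hold)
  shift <- wmMode * fact - targets[1]
  shift2 <- csfMode * fact - targets[2]
  if (abs(shift - shift2) > 1e-6 * (1 + abs(shift)))
    ## orientation violated: fall back to the exact two-point solution
    ## (fact may then differ from the printed |dRef|/|dMode| form)
    {
      fact <- (targets[1] - targets[2]) / (wmMode - csfMode)
      shift <- wmMode * fact - targets[1]
    }
  new("RescaleParams", wmMode = wmMode, csfMode = csfMode,
      fact = fact, shift = shift, kind = kind,
      refs = c(refs[["ref1"]], refs[["ref2"]]))
}

#' Apply recalibration parameters to a volume
#'
#' Voxelwise \code{out = in * fact - shift}; a strictly increasing affine map,
#' so intensity rank order is preserved.
#'
#' @param vol a \linkS4class{BrainVolume}.
#' @param params a \linkS4class{RescaleParams}.
#' @return the recalibrated \linkS4class{BrainVolume}.
#' @export
applyRescale <- function(vol, params) {
  stopifnot(is.finite(params@fact), is.finite(params@shift))
  brainVolume(vol@data * params@fact - params@shift,
              vol@spacing, vol@origin, vol@frame)
}

#' Repair negative voxels by neighborhood averaging
#'
#' Recalibration can push some tissue voxels below zero. Each in-mask voxel
#' with a negative intensity is replaced by the mean of its in-mask,
#' non-negative face neighbors, computed from the original (pre-repair)
#' volume in a single pass. Voxels with no eligible neighbor are set to 0 and
#' counted in the \code{repaired} attribute.
#'
#' @param vol a \linkS4class{BrainVolume}.
#' @param mask a \linkS4class{MaskVolume}; voxels outside it are untouched.
#' @return the repaired volume, with attribute-like log in
#'   \code{attr(volData(x), ...)} avoided: counts are reported via a message.
#' @export
repairNegative <- function(vol, mask) {
  if (sum(mask@data) == 0) stop("empty mask")
  d <- vol@data
  idx <- which(mask@data != 0 & d < 0)
  if (length(idx) == 0L) return(vol)
  nb <- neighborIndexMatrix(idx, dim(d))
  vals <- matrix(d[nb], nrow(nb), 6L)
  inmask <- matrix(mask@data[nb] != 0, nrow(nb), 6L)
  ok <- !is.na(nb) & inmask & !is.na(vals) & vals >= 0
  vals[!ok] <- NA_real_
  repl <- rowMeans(vals, na.rm = TRUE)
  orphan <- !is.finite(repl)
  if (any(orphan)) {
    message(sum(orphan), " negative voxel(s) had no eligible neighbor; set to 0")
    repl[orphan] <- 0
  }
  d[idx] <- repl
  brainVolume(d, vol@spacing, vol@origin, vol@frame)
}

#' Compute the T1/T2 RATIO image with extreme-voxel repair
#'
#' Voxelwise quotient of the recalibrated T1 by the recalibrated T2 inside
#' the mask (0 outside). Non-positive T2 voxels are first replaced by the
#' smallest positive in-mask T2 value. Ratio voxels above the in-mask 99th
#' percentile are then replaced, in a single pass, by the mean of their
#' in-mask face neighbors whose ratio is at or below that percentile
#' (voxels with no eligible neighbor are set to the percentile value).
#'
#' @param t1cal,t2cal recalibrated volumes on one grid.
#' @param mask analysis \linkS4class{MaskVolume}.
#' @param percentile upper repair percentile (default 99).
#' @return the RATIO \linkS4class{BrainVolume}.
#' @export
computeRatio <- function(t1cal, t2cal, mask, percentile = 99) {
  if (!identical(dim(t1cal@data), dim(t2cal@data)) ||
      !identical(dim(t1cal@data), dim(mask@data)))
    stop("T1, T2 and mask grids differ")
  idx <- which(mask@data != 0)
  if (length(idx) == 0L) stop("empty mask")
  t2v <- t2cal@data[idx]
  if (all(t2v <= 0)) stop("recalibrated T2 is non-positive everywhere in mask")
  if (any(t2v <= 0)) {
    minpos <- min(t2v[t2v > 0])
    message(sum(t2v <= 0), " non-positive T2 voxel(s) replaced by ", minpos)
    t2v[t2v <= 0] <- minpos
  }
  r <- numeric(length(idx))
  r <- t1cal@data[idx] / t2v
  out <- array(0, dim(mask@data))
  out[idx] <- r
  ## 99th-percentile repair, computed within the mask
  p99 <- stats::quantile(r, percentile / 100, names = FALSE)
  hi <- idx[r > p99]
  if (length(hi) > 0L) {
    nb <- neighborIndexMatrix(hi, dim(out))
    vals <- matrix(out[nb], nrow(nb), 6L)
    inmask <- matrix(mask@data[nb] != 0, nrow(nb), 6L)
    ok <- !is.na(nb) & inmask & !is.na(vals) & vals <= p99
    vals[!ok] <- NA_real_
    repl <- rowMeans(vals, na.rm = TRUE)
    repl[!is.finite(repl)] <- p99
    out[hi] <- repl
  }
  brainVolume(out, mask@spacing, mask@origin, mask@frame)
}

#' Select high-probability tissue voxels and estimate both channel modes
#'
#' Thresholds the white-matter and CSF probability maps at >= 0.9 to select
#' high-confidence voxels, extracts their intensities from one channel, and
#' returns the vessel-excluded histogram modes (above-99th-percentile voxels
#' excluded for T1, below-1st-percentile for T2).
#'
#' @param vol T1 or T2 \linkS4class{BrainVolume} (pre-recalibration).
#' @param wmProb,csfProb tissue probability \linkS4class{BrainVolume}s.
#' @param kind "T1" or "T2".
#' @param probThreshold high-probability cutoff (default 0.9, inclusive).
#' @return named numeric(2): \code{wm}, \code{csf} modes.
#' @export
tissueModes <- function(vol, wmProb, csfProb, kind = c("T1", "T2"),
                        probThreshold = 0.9) {
  kind <- match.arg(kind)
  wmv <- vol@data[wmProb@data >= probThreshold]
  csfv <- vol@data[csfProb@data >= probThreshold]
  if (kind == "T1") {
    c(wm = histogramMode(wmv, excludeHigh = 99),
      csf = histogramMode(csfv, excludeHigh = 99))
  } else {
    c(wm = histogramMode(wmv, excludeLow = 1),
      csf = histogramMode(csfv, excludeLow = 1))
  }
}

#' Write recalibration parameters as a JSON QC sidecar
#'
#' @param params list of \linkS4class{RescaleParams} (e.g. T1 and T2).
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeRescaleSidecar <- function(params, path) {
  x <- lapply(params, function(p)
    list(kind = p@kind, wm_mode = p@wmMode, csf_mode = p@csfMode,
         fact = p@fact, shift = p@shift, ref1 = p@refs[1], ref2 = p@refs[2]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
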