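#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm (length 3, recycled from length 1).
#' @param origin world position of voxel (1,1,1).
#' @param frame space tag, "subject" or "template".
#' @return A \linkS4class{BrainVolume}.
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        frame = "subject") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), frame = frame)
}

#' Construct a MaskVolume
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams brainVolume
#' @return A \linkS4class{MaskVolume}.
#' @export
maskVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       frame = "subject") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("MaskVolume", data = (data != 0) + 0, spacing = as.numeric(spacing),
      origin = as.numeric(origin), frame = frame)
}

#' Construct a LabelVolume
#'
#' @param data 3D integer array (0 background, 1..L labels).
#' @param labelNames character vector of L unique names.
#' @inheritParams brainVolume
#' @return A \linkS4class{LabelVolume}.
#' @export
labelVolume <- function(data, labelNames, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), frame = "subject") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("LabelVolume", data = data, labelNames = labelNames,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      frame = frame)
}

#' @rdname volData
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' Accessors for volume slots
#'
#' \code{volData} returns the raw 3D array, \code{volSpacing} the voxel size
#' in mm, \code{volDim} the grid dims.
#'
#' @param x a \linkS4class{BrainVolume} (or subclass).
#' @return array / numeric(3) / integer(3).
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname volData
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' @rdname volData
#' @export
setMethod("volSpacing", "BrainVolume", function(x) x@spacing)

#' @rdname volData
#' @export
volDim <- function(x) dim(x@data)

#' @rdname volData
#' @export
labelNames <- function(x) x@labelNames

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a .nii or .nii.gz file containing a single 3D image.
#' @param frame space tag attached to the returned volume.
#' @return A \linkS4class{BrainVolume}.
#' @export
readVolume <- function(path, frame = "subject") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected 3D image, got %dD: %s", length(d), path))
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  storage.mode(arr) <- "double"
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite voxels: %s", nbad, path))
  xf <- RNifti::xform(img)
  brainVolume(arr, spacing = RNifti::pixdim(img)[1:3],
              origin = xf[1:3, 4], frame = frame)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 32-bit float for intensity volumes and 32-bit int for
#' \linkS4class{LabelVolume}/\linkS4class{MaskVolume}. The grid-to-world
#' transform is written to both qform and sform (axis-aligned).
#'
#' @param vol a \linkS4class{BrainVolume} (or subclass).
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype NIfTI on-disk type; default "float" ("int32" for label and
#'   mask volumes, "double" to round-trip doubles bit-exactly).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = NULL) {
  if (!dir.exists(dirname(path)))
    stop("directory not writable: ", dirname(path))
  if (is.null(datatype))
    datatype <- if (is(vol, "LabelVolume") || is(vol, "MaskVolume"))
      "int32" else "float"
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  m[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Extract in-mask intensities in canonical raster order
#'
#' Raster order (x fastest, then y, then z) is the canonical voxel ordering
#' of the whole pipeline; the returned index vector allows scattering results
#' back onto the grid with \code{\link{scatterValues}}.
#'
#' @param vol a \linkS4class{BrainVolume}.
#' @param mask a \linkS4class{MaskVolume} on the same grid.
#' @return list with \code{values} (numeric) and \code{index} (integer linear
#'   grid indices).
#' @export
maskedValues <- function(vol, mask) {
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("volume and mask grids differ")
  idx <- which(mask@data != 0)
  if (length(idx) == 0L) stop("empty mask")
  list(values = as.numeric(vol@data[idx]), index = idx)
}

#' Scatter values back onto a grid
#'
#' Inverse of \code{\link{maskedValues}}: writes \code{values} at linear
#' indices \code{index} of a copy of \code{vol}.
#'
#' @param vol volume supplying the grid and out-of-mask values.
#' @param index integer linear indices.
#' @param values numeric vector, same length as \code{index}.
#' @return A \linkS4class{BrainVolume}.
#' @export
scatterValues <- function(vol, index, values) {
  stopifnot(length(index) == length(values))
  d <- vol@data
  d[index] <- values
  brainVolume(d, vol@spacing, vol@origin, vol@frame)
}

#' Face-adjacent (6-connectivity) neighbors of a voxel
#'
#' "First-order neighborhood" is fixed to face adjacency: the smallest
#' standard 3D neighborhood. Out-of-bounds neighbors are clipped.
#'
#' @param idx integer(3) voxel index (1-based).
#' @param shape integer(3) grid dims.
#' @return integer matrix with one row per in-bounds neighbor.
#' @export
firstOrderNeighbors <- function(idx, shape) {
  idx <- as.integer(idx); shape <- as.integer(shape)
  if (any(idx < 1L) || any(idx > shape)) stop("voxel index out of bounds")
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  nb <- sweep(offs, 2L, idx, "+")
  keep <- nb[, 1] >= 1L & nb[, 1] <= shape[1] &
          nb[, 2] >= 1L & nb[, 2] <= shape[2] &
          nb[, 3] >= 1L & nb[, 3] <= shape[3]
  nb[keep, , drop = FALSE]
}

## ---- internal grid helpers -------------------------------------------------

## linear indices of the 6 face neighbors for a set of linear indices;
## returns an (n x 6) matrix with NA where the neighbor falls outside the grid
neighborIndexMatrix <- function(index, shape) {
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  i0 <- index - 1L
  x <- i0 %% n1
  y <- (i0 %/% n1) %% n2
  z <- i0 %/% (n1 * n2)
  out <- matrix(NA_integer_, length(index), 6L)
  out[, 1] <- ifelse(x > 0L,      index - 1L,        NA_integer_)
  out[, 2] <- ifelse(x < n1 - 1L, index + 1L,        NA_integer_)
  out[, 3] <- ifelse(y > 0L,      index - n1,        NA_integer_)
  out[, 4] <- ifelse(y < n2 - 1L, index + n1,        NA_integer_)
  out[, 5] <- ifelse(z > 0L,      index - n1 * n2,   NA_integer_)
  out[, 6] <- ifelse(z < n3 - 1L, index + n1 * n2,   NA_integer_)
  out
}

## precompute trilinear corner indices and weights for a set of continuous
## voxel coords (shared across any number of arrays sampled at the same
## positions); coordinates are clamped to the grid
trilinearPrep <- function(d, coords) {
  cx <- pmin(pmax(coords[, 1], 1), d[1])
  cy <- pmin(pmax(coords[, 2], 1), d[2])
  cz <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(cx), d[1] - 1L); if (d[1] == 1L) x0[] <- 1
  y0 <- pmin(floor(cy), d[2] - 1L); if (d[2] == 1L) y0[] <- 1
  z0 <- pmin(floor(cz), d[3] - 1L); if (d[3] == 1L) z0[] <- 1
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  n12 <- d[1] * d[2]
  base <- (x0 - 1) + (y0 - 1) * d[1] + (z0 - 1) * n12 + 1
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) d[1] else 0L
  sz <- if (d[3] > 1L) n12 else 0L
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  list(base = base, sx = sx, sy = sy, sz = sz,
       w000 = gx * gy * gz, w100 = fx * gy * gz,
       w010 = gx * fy * gz, w110 = fx * fy * gz,
       w001 = gx * gy * fz, w101 = fx * gy * fz,
       w011 = gx * fy * fz, w111 = fx * fy * fz)
}

## sample one array using precomputed trilinear weights
trilinearApply <- function(arr, p) {
  b <- p$base
  p$w000 * arr[b] +
  p$w100 * arr[b + p$sx] +
  p$w010 * arr[b + p$sy] +
  p$w110 * arr[b + p$sx + p$sy] +
  p$w001 * arr[b + p$sz] +
  p$w101 * arr[b + p$sx + p$sz] +
  p$w011 * arr[b + p$sy + p$sz] +
  p$w111 * arr[b + p$sx + p$sy + p$sz]
}

## trilinear sampling of a 3D array at continuous voxel coords (n x 3 matrix,
## 1-based); coordinates are clamped to the grid
interpTrilinear <- function(arr, coords) {
  trilinearApply(arr, trilinearPrep(dim(arr), coords))
}

## nearest-neighbor sampling at continuous voxel coords
interpNearest <- function(arr, coords) {
  d <- dim(arr)
  x <- pmin(pmax(round(coords[, 1]), 1), d[1])
  y <- pmin(pmax(round(coords[, 2]), 1), d[2])
  z <- pmin(pmax(round(coords[, 3]), 1), d[3])
  arr[(x - 1) + (y - 1) * d[1] + (z - 1) * d[1] * d[2] + 1]
}

## identity grid coordinates of a shape, as an (n x 3) matrix in raster order
gridCoords <- function(shape) {
  cbind(rep.int(seq_len(shape[1]), shape[2] * shape[3]),
        rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
        rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}

## separable 3D Gaussian smoothing (sigma in voxels); truncated-kernel
## matrix convolution with edge renormalization, exact and fast at small grids
smoothArray3D <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- d[ax]
    r <- min(n - 1L, ceiling(3 * s))
    if (r < 1L) next
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = s)
    K[abs(outer(seq_len(n), seq_len(n), "-")) > r] <- 0
    K <- K / rowSums(K)
    if (ax == 1L) {
      arr <- array(K %*% matrix(arr, d[1]), d)
    } else if (ax == 2L) {
      tmp <- aperm(arr, c(2, 1, 3))
      tmp <- array(K %*% matrix(tmp, d[2]), c(d[2], d[1], d[3]))
      arr <- aperm(tmp, c(2, 1, 3))
    } else {
      tmp <- aperm(arr, c(3, 1, 2))
      tmp <- array(K %*% matrix(tmp, d[3]), c(d[3], d[1], d[2]))
      arr <- aperm(tmp, c(2, 3, 1))
    }
  }
  arr
}

## block-mean downsampling by an integer factor (pads by edge replication
## implicitly via index clamping)
downsampleArray <- function(arr, factor) {
  if (factor == 1L) return(arr)
  d <- dim(arr)
  nd <- pmax(1L, as.integer(ceiling(d / factor)))
  ix <- pmin(rep(seq_len(nd[1] * factor), length.out = nd[1] * factor), d[1])
  co <- gridCoords(nd)
  ## average the factor^3 children of each coarse voxel
  out <- numeric(nrow(co))
  cnt <- 0L
  for (ox in seq_len(factor)) for (oy in seq_len(factor)) for (oz in seq_len(factor)) {
    x <- pmin((co[, 1] - 1L) * factor + ox, d[1])
    y <- pmin((co[, 2] - 1L) * factor + oy, d[2])
    z <- pmin((co[, 3] - 1L) * factor + oz, d[3])
    out <- out + arr[(x - 1) + (y - 1) * d[1] + (z - 1) * d[1] * d[2] + 1]
    cnt <- cnt + 1L
  }
  array(out / cnt, nd)
}

## trilinear upsampling of a coarse array onto a fine grid of dims `shape`,
## where the coarse grid was obtained with `downsampleArray(.., factor)`
upsampleArray <- function(arr, shape, factor) {
  co <- gridCoords(shape)
  ## fine voxel centers in coarse voxel coordinates
  cc <- cbind((co[, 1] - 0.5) / factor + 0.5,
              (co[, 2] - 0.5) / factor + 0.5,
              (co[, 3] - 0.5) / factor + 0.5)
  array(interpTrilinear(arr, cc), shape)
}
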