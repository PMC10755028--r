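#' @import methods
NULL

#' BrainVolume: a 3D scalar image on a regular grid
#'
#' The common carrier for T1, T2, RATIO, tissue-probability, prior and
#' Jacobian images. Holds the voxel data, voxel spacing in mm, the world-space
#' origin of the first voxel, and a frame tag ("subject" or "template") so
#' that volumes from different spaces are never mixed silently. All volumes
#' belonging to one subject must share one grid; the pipeline never resamples
#' implicitly.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size in mm per axis (all > 0).
#' @slot origin numeric(3), world coordinates of voxel (1,1,1).
#' @slot frame character(1) space tag, e.g. "subject" or "template".
#' @export
setClass("BrainVolume",
         representation(data = "array", spacing = "numeric",
                        origin = "numeric", frame = "character"),
         prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   frame = "subject"))

setValidity("BrainVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return(sprintf("expected 3D data, got %dD", length(dim(d))))
  if (any(dim(d) < 1L)) return("all three dims must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  nbad <- sum(!is.finite(d))
  if (nbad > 0L)
    return(sprintf("data contains %d non-finite voxels", nbad))
  TRUE
})

#' MaskVolume: a binary 3D mask
#'
#' @slot data array of 0/1 values on the same grid metadata as
#'   \linkS4class{BrainVolume}.
#' @export
setClass("MaskVolume", contains = "BrainVolume")

setValidity("MaskVolume", function(object) {
  if (!all(object@data %in% c(0, 1)))
    return("mask values must be 0 or 1")
  TRUE
})

#' LabelVolume: an integer-labelled 3D volume
#'
#' Voxel value 0 is background; values 1..L index into \code{labelNames}.
#'
#' @slot labelNames character vector of L unique region/class names.
#' @export
setClass("LabelVolume", contains = "BrainVolume",
         representation(labelNames = "character"))

setValidity("LabelVolume", function(object) {
  d <- object@data
  if (any(d != round(d))) return("labels must be integers")
  if (any(d < 0)) return("labels must be >= 0")
  L <- length(object@labelNames)
  if (max(d) > L)
    return(sprintf("label %d exceeds number of label names (%d)", max(d), L))
  if (anyDuplicated(object@labelNames)) return("label names must be unique")
  TRUE
})

#' RescaleParams: two-point linear intensity recalibration
#'
#' The affine map \code{out = in * fact - shift} sending the white-matter and
#' CSF histogram modes of one image to the fixed reference intensities
#' (T1: wm -> ref1, csf -> ref2; T2: wm -> ref2, csf -> ref1).
#'
#' @slot wmMode,csfMode histogram modes the map was fitted on.
#' @slot fact scale factor (> 0); equals |ref1 - ref2| / |wmMode - csfMode|.
#' @slot shift offset subtracted after scaling.
#' @slot kind "T1" or "T2".
#' @slot refs numeric(2), the (ref1, ref2) targets used.
#' @export
setClass("RescaleParams",
         representation(wmMode = "numeric", csfMode = "numeric",
                        fact = "numeric", shift = "numeric",
                        kind = "character", refs = "numeric"))

setValidity("RescaleParams", function(object) {
  if (object@wmMode == object@csfMode) return("wmMode must differ from csfMode")
  if (!is.finite(object@fact) || object@fact <= 0) return("fact must be > 0")
  if (!object@kind %in% c("T1", "T2")) return("kind must be 'T1' or 'T2'")
  TRUE
})

#' FeatureMatrix: z-scored in-mask voxel intensities
#'
#' Rows are in-mask voxels in canonical raster order (x fastest); columns are
#' the selected channels (subset of T1, T2, RATIO), each z-scored over rows.
#'
#' @slot x numeric matrix (voxels x channels).
#' @slot channels character vector naming the columns.
#' @slot voxelIndex integer vector of linear grid indices for each row.
#' @slot dim integer(3) grid dims, so results can be scattered back.
#' @export
setClass("FeatureMatrix",
         representation(x = "matrix", channels = "character",
                        voxelIndex = "integer", dim = "integer"))

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@x) != length(object@channels))
    return("channels must name every column")
  if (nrow(object@x) != length(object@voxelIndex))
    return("voxelIndex must index every row")
  if (any(!is.finite(object@x))) return("feature matrix has non-finite entries")
  TRUE
})

#' ClusterModel: fitted k-means tissue clustering
#'
#' @slot k number of clusters.
#' @slot centroids k x n_channels matrix in z-score space.
#' @slot labels per-voxel cluster id in 1..k (same order as the
#'   \linkS4class{FeatureMatrix} rows).
#' @slot sqDistances per-voxel squared Euclidean distance to own centroid.
#' @slot stdDistance per-voxel standardized proximity in [0,1] (1 = at the
#'   centroid, 0 = farthest voxel of the cluster); filled by
#'   \code{\link{standardizeDistances}}.
#' @slot objective total within-cluster sum of squares.
#' @slot seed RNG seed the fit used.
#' @slot channels channel names.
#' @slot voxelIndex,dim grid bookkeeping copied from the feature matrix.
#' @export
setClass("ClusterModel",
         representation(k = "integer", centroids = "matrix",
                        labels = "integer", sqDistances = "numeric",
                        stdDistance = "numeric", objective = "numeric",
                        seed = "integer", channels = "character",
                        voxelIndex = "integer", dim = "integer"))

setValidity("ClusterModel", function(object) {
  if (any(object@labels < 1L | object@labels > object@k))
    return("labels must lie in 1..k")
  if (length(object@stdDistance) &&
      (min(object@stdDistance) < 0 || max(object@stdDistance) > 1))
    return("stdDistance must lie in [0,1]")
  if (abs(object@objective - sum(object@sqDistances)) >
      1e-6 * (1 + object@objective))
    return("objective must equal the sum of squared distances")
  TRUE
})

#' VelocityField: stationary velocity field of a diffeomorphism
#'
#' @slot v 4D array (x, y, z, 3) of displacement rates in voxel units.
#' @slot spacing voxel spacing (mm).
#' @export
setClass("VelocityField",
         representation(v = "array", spacing = "numeric"))

setValidity("VelocityField", function(object) {
  if (length(dim(object@v)) != 4L || dim(object@v)[4] != 3L)
    return("v must be a (x,y,z,3) array")
  if (any(!is.finite(object@v))) return("velocity must be finite")
  TRUE
})

#' DeformationField: dense coordinate mapping between spaces
#'
#' Stores the displacement \code{disp} so that the mapped position of output
#' grid voxel x is x + disp(x) (voxel units). When produced by
#' \code{\link{exponentiate}} the generating velocity is retained so the
#' exact inverse exp(-v) is available.
#'
#' @slot disp 4D array (x, y, z, 3) of displacements in voxel units.
#' @slot from,to frame tags (the field lives on the `from` grid and returns
#'   coordinates in the `to` space).
#' @slot velocity the generating \linkS4class{VelocityField}, or NULL.
#' @export
setClass("DeformationField",
         representation(disp = "array", from = "character", to = "character",
                        velocity = "ANY"),
         prototype(from = "template", to = "subject", velocity = NULL))

setValidity("DeformationField", function(object) {
  if (length(dim(object@disp)) != 4L || dim(object@disp)[4] != 3L)
    return("disp must be a (x,y,z,3) array")
  if (any(!is.finite(object@disp))) return("displacement must be finite")
  TRUE
})

#' PriorSet: probabilistic cluster group averages
#'
#' Five probabilistic volumes (one per cluster) in one space, stored as a
#' (x, y, z, k) array, plus the evaluation threshold used by the
#' misclassification index.
#'
#' @slot maps 4D array of probabilities in [0,1].
#' @slot frame space tag ("template" or "subject").
#' @slot evalThreshold probability threshold used for misclassification
#'   indexing (default 0.3).
#' @export
setClass("PriorSet",
         representation(maps = "array", frame = "character",
                        evalThreshold = "numeric"),
         prototype(frame = "template", evalThreshold = 0.3))

setValidity("PriorSet", function(object) {
  if (length(dim(object@maps)) != 4L)
    return("maps must be a 4D (x,y,z,cluster) array")
  if (min(object@maps) < -1e-9 || max(object@maps) > 1 + 1e-9)
    return("prior probabilities must lie in [0,1]")
  k <- dim(object@maps)[4]
  s <- apply(object@maps, c(1, 2, 3), sum)
  if (max(s) > 1 + 1e-6)
    return("per-voxel sum of prior probabilities must be <= 1")
  TRUE
})

#' TemplateSet: groupwise template with per-subject deformations
#'
#' @slot template 4D (x,y,z,k) probabilistic template.
#' @slot forward list of \linkS4class{DeformationField}s, template -> subject.
#' @slot inverse list of \linkS4class{DeformationField}s, subject -> template.
#' @slot ssdTrace per-outer-iteration group mean SSD to the template.
#' @slot nIters outer iterations performed.
#' @export
setClass("TemplateSet",
         representation(template = "array", forward = "list",
                        inverse = "list", ssdTrace = "numeric",
                        nIters = "integer"))

setValidity("TemplateSet", function(object) {
  if (length(object@forward) != length(object@inverse))
    return("one forward/inverse deformation pair per subject required")
  if (min(object@template) < -1e-9 || max(object@template) > 1 + 1e-9)
    return("template values must lie in [0,1]")
  TRUE
})

#' FinalSegmentation: probabilistic final segmentation of one subject
#'
#' @slot maps 4D (x,y,z,k) array of final cluster probabilities.
#' @slot hardLabels \linkS4class{LabelVolume} of argmax labels (0 where all
#'   probabilities are 0).
#' @slot reassignLog list with per-rule reassignment voxel counts.
#' @export
setClass("FinalSegmentation",
         representation(maps = "array", hardLabels = "LabelVolume",
                        reassignLog = "list"))

setValidity("FinalSegmentation", function(object) {
  if (min(object@maps) < -1e-9 || max(object@maps) > 1 + 1e-9)
    return("final probabilities must lie in [0,1]")
  TRUE
})

#' PhantomConfig: synthetic brainstem cohort settings
#'
#' Defaults define the study conditions the synthetic cohorts emulate: five
#' tissue classes whose T1 ordering is iron-rich/white > white > gray >
#' CSF-partial shell (and reversed for T2), 5\% multiplicative channel noise,
#' a smooth bias field of amplitude 5\%, smooth random diffeomorphic shape
#' variation of ~1.5 voxels, and a linear age-linked contraction of designated
#' atrophy ROIs of -0.3\%/year.
#'
#' @slot shape integer(3) grid dims (default 48^3).
#' @slot nClasses number of tissue classes (5).
#' @slot classMeansT1,classMeansT2 named per-class mean intensities
#'   (iron, shell, gray_pag, white, gray_nuclei) plus csf/background handled
#'   separately via csfT1/csfT2/bgT1/bgT2.
#' @slot csfT1,csfT2,bgT1,bgT2 intensities of the surrounding CSF rim and
#'   background.
#' @slot noiseSd numeric(2) fractional (multiplicative) noise SD for (T1, T2).
#' @slot biasAmplitude max fractional deviation of the multiplicative bias
#'   field (in [0,1)).
#' @slot biasSmooth Gaussian scale of the bias field (voxels).
#' @slot deformSd random velocity-field magnitude (voxels).
#' @slot deformSmooth Gaussian scale of the random velocity (voxels).
#' @slot ageBeta per-year fractional volume change in atrophy ROIs.
#' @slot ageCenter age (years) at which the atrophy factor is 1.
#' @slot atrophyRois names of ROIs receiving the age effect.
#' @slot seed master seed.
#' @export
setClass("PhantomConfig",
         representation(shape = "integer", nClasses = "integer",
                        classMeansT1 = "numeric", classMeansT2 = "numeric",
                        csfT1 = "numeric", csfT2 = "numeric",
                        bgT1 = "numeric", bgT2 = "numeric",
                        noiseSd = "numeric", biasAmplitude = "numeric",
                        biasSmooth = "numeric", deformSd = "numeric",
                        deformSmooth = "numeric", ageBeta = "numeric",
                        ageCenter = "numeric", atrophyRois = "character",
                        seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 16L))
    return("shape must be 3 dims of at least 16 voxels")
  if (anyDuplicated(object@classMeansT1) || anyDuplicated(object@classMeansT2))
    return("class means must be distinct per channel")
  if (any(object@noiseSd < 0)) return("noiseSd must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    return("biasAmplitude must lie in [0,1)")
  if (object@deformSd < 0 || object@deformSmooth < 0)
    return("deformation parameters must be >= 0")
  TRUE
})

#' SubjectGroundTruth: one synthetic subject with full ground truth
#'
#' @slot id subject identifier.
#' @slot t1,t2 \linkS4class{BrainVolume} intensity images.
#' @slot tissueMaps list of gm/wm/csf probability volumes.
#' @slot brainstemMask \linkS4class{MaskVolume} of the five-class tissue
#'   region (the analogue of the MNI brainstem/thalamus label).
#' @slot trueLabels \linkS4class{LabelVolume} of the 5 tissue classes.
#' @slot roiAtlas \linkS4class{LabelVolume} of morphometry ROIs (subject
#'   space).
#' @slot age age in years.
#' @slot trueDeformation \linkS4class{DeformationField}, template -> subject.
#' @slot seed per-subject seed.
#' @export
setClass("SubjectGroundTruth",
         representation(id = "character", t1 = "BrainVolume",
                        t2 = "BrainVolume", tissueMaps = "list",
                        brainstemMask = "MaskVolume",
                        trueLabels = "LabelVolume", roiAtlas = "LabelVolume",
                        age = "numeric", trueDeformation = "DeformationField",
                        seed = "integer"))

setValidity("SubjectGroundTruth", function(object) {
  if (object@age < 0 || object@age > 120) return("age must lie in [0,120]")
  m <- object@brainstemMask@data
  lab <- object@trueLabels@data
  if (any((lab > 0) != (m > 0)))
    return("true labels must partition the brainstem mask")
  TRUE
})

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d [%s], spacing %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3], object@frame,
              object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %dx%dx%d, %d labels, %d labelled voxels\n",
              d[1], d[2], d[3], length(object@labelNames),
              sum(object@data > 0)))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel k=%d on %d voxels, channels {%s}, objective %.4g\n",
              object@k, length(object@labels),
              paste(object@channels, collapse = ","), object@objective))
})

setMethod("show", "RescaleParams", function(object) {
  cat(sprintf("RescaleParams [%s]: modes wm=%.4g csf=%.4g -> fact=%.6g shift=%.6g\n",
              object@kind, object@wmMode, object@csfMode,
              object@fact, object@shift))
})

setMethod("show", "PriorSet", function(object) {
  d <- dim(object@maps)
  cat(sprintf("PriorSet %dx%dx%d, %d clusters [%s], eval threshold %.2g\n",
              d[1], d[2], d[3], d[4], object@frame, object@evalThreshold))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  mag <- sqrt(rowSums(matrix(object@disp, ncol = 3)^2))
  cat(sprintf("DeformationField %dx%dx%d (%s -> %s), mean |disp| %.3g vox, max %.3g vox\n",
              d[1], d[2], d[3], object@from, object@to, mean(mag), max(mag)))
})
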