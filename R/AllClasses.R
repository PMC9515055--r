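#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib BoneBEM, .registration = TRUE
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Virtual parent of all volumetric containers
#'
#' Carries the voxel spacing (mm per voxel along x, y, z) and the 4x4
#' voxel-to-world affine shared by every concrete volume class.
#'
#' @slot spacing numeric(3), voxel size in mm, all positive.
#' @slot affine 4x4 voxel-to-world transform.
#' @keywords internal
setClass("Volume3D", representation("VIRTUAL",
  spacing = "numeric", affine = "matrix"))

setValidity("Volume3D", function(object) {
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be three positive finite values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("'affine' must be a 4x4 matrix")
  TRUE
})

#' CT volume in Hounsfield units
#'
#' A 3D scalar field of Hounsfield units indexed (x, y, z), the storage order
#' of NIfTI, with per-axis voxel spacing.
#'
#' @slot voxels 3D numeric array of HU values, all finite.
#' @export
setClass("CTVolume", contains = "Volume3D",
         representation(voxels = "array"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("'voxels' must be a 3D array")
  if (!all(is.finite(object@voxels)))
    return("all voxel values must be finite")
  TRUE
})

#' Voxelwise multi-class label volume
#'
#' Integer labels on a 3D grid; 0 is background, 1..N-1 are distinct bones,
#' where N (\code{nClasses}) counts the background class.
#'
#' @slot labels 3D integer array with values in [0, nClasses - 1].
#' @slot nClasses total class count N including background.
#' @export
setClass("LabelVolume", contains = "Volume3D",
         representation(labels = "array", nClasses = "integer"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("'labels' must be a 3D array")
  if (!is.integer(object@labels))
    return("'labels' must have integer storage mode")
  if (length(object@nClasses) != 1L || is.na(object@nClasses) ||
      object@nClasses < 1L)
    return("'nClasses' must be a single positive integer")
  r <- range(object@labels)
  if (r[1] < 0L || r[2] > object@nClasses - 1L)
    return(sprintf("label values must lie in [0, %d]; observed [%d, %d]",
                   object@nClasses - 1L, r[1], r[2]))
  TRUE
})

#' Binary bone-tissue mask
#'
#' A 3D field in {0, 1}; 1 marks bone tissue.  This is the binary
#' background/bone-tissue segmentation used to guide BEM inference.
#'
#' @slot mask 3D integer array with values exactly 0 or 1.
#' @export
setClass("BinaryMask", contains = "Volume3D",
         representation(mask = "array"))

setValidity("BinaryMask", function(object) {
  if (length(dim(object@mask)) != 3L)
    return("'mask' must be a 3D array")
  if (!is.integer(object@mask))
    return("'mask' must have integer storage mode")
  if (!all(object@mask == 0L | object@mask == 1L))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' Per-voxel class-probability volume
#'
#' Stores a length-N probability vector per voxel as a 4D array
#' (x, y, z, class), class index 1 of the array corresponding to the
#' background class 0.
#'
#' @slot probs 4D numeric array; entries in [0, 1], per-voxel sums within
#'   1e-5 of 1.
#' @slot nClasses total class count N (fourth array extent).
#' @export
setClass("ProbabilityVolume", contains = "Volume3D",
         representation(probs = "array", nClasses = "integer"))

setValidity("ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L)
    return("'probs' must be a 4D array (x, y, z, class)")
  if (d[4] != object@nClasses)
    return("fourth extent of 'probs' must equal 'nClasses'")
  if (any(object@probs < -1e-8) || any(object@probs > 1 + 1e-8))
    return("probabilities must lie in [0, 1]")
  nv <- prod(d[1:3])
  s <- rowSums(matrix(object@probs, nrow = nv))
  if (any(abs(s - 1) > 1e-5))
    return("per-voxel probabilities must sum to 1 within 1e-5")
  TRUE
})

.default_affine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing per-axis voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by \code{spacing}.
#' @return A \linkS4class{CTVolume}.
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(voxels) <- "double"
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      affine = if (is.null(affine)) .default_affine(spacing) else affine)
}

#' Construct a label volume
#'
#' @param labels 3D array of non-negative integer class ids (0 = background).
#' @param nClasses total class count N including background; defaults to
#'   \code{max(labels) + 1}.
#' @inheritParams CTVolume
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, nClasses = NULL, spacing = c(1, 1, 1),
                        affine = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(nClasses)) nClasses <- max(labels, 0L) + 1L
  new("LabelVolume", labels = labels, nClasses = as.integer(nClasses),
      spacing = as.numeric(spacing),
      affine = if (is.null(affine)) .default_affine(spacing) else affine)
}

#' Construct a binary bone-tissue mask
#'
#' @param mask 3D array with values 0/1.
#' @inheritParams CTVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(mask, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(mask) <- "integer"
  new("BinaryMask", mask = mask, spacing = as.numeric(spacing),
      affine = if (is.null(affine)) .default_affine(spacing) else affine)
}

#' Construct a probability volume
#'
#' @param probs 4D array (x, y, z, class) of per-voxel class probabilities.
#' @inheritParams CTVolume
#' @return A \linkS4class{ProbabilityVolume}.
#' @export
ProbabilityVolume <- function(probs, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(probs) <- "double"
  new("ProbabilityVolume", probs = probs, nClasses = as.integer(dim(probs)[4]),
      spacing = as.numeric(spacing),
      affine = if (is.null(affine)) .default_affine(spacing) else affine)
}
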