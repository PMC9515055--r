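#' Voxel data of a CT volume
#' @param x a \linkS4class{CTVolume}.
#' @return 3D numeric array of Hounsfield units.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Label array of a label volume
#' @param x a \linkS4class{LabelVolume}.
#' @return 3D integer array.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' Mask array of a binary mask
#' @param x a \linkS4class{BinaryMask}.
#' @return 3D integer array in \{0, 1\}.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Probability array of a probability volume
#' @param x a \linkS4class{ProbabilityVolume}.
#' @return 4D numeric array (x, y, z, class).
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))

#' Voxel spacing in mm
#' @param x a volume object.
#' @return numeric(3).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Total class count N (including background)
#' @param x a \linkS4class{LabelVolume} or \linkS4class{ProbabilityVolume}.
#' @return integer(1).
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Resample a volume to a new voxel spacing
#'
#' CT volumes are interpolated trilinearly; label volumes and masks by
#' nearest neighbour (ties rounded toward the origin), so the output label
#' set is always a subset of the input's.  The output grid shape is
#' \code{round(dim * spacing / targetSpacing)}.
#'
#' @param x a \linkS4class{CTVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{BinaryMask}.
#' @param targetSpacing numeric(3) of positive target voxel sizes in mm (a
#'   single value is recycled, e.g. \code{2} for 2 mm isotropic).
#' @return A volume of the same class as \code{x}.
#' @export
setGeneric("resampleVolume", function(x, targetSpacing)
  standardGeneric("resampleVolume"))

#' @describeIn voxels CT accessor
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @describeIn labelArray label accessor
setMethod("labelArray", "LabelVolume", function(x) x@labels)

#' @describeIn maskArray mask accessor
setMethod("maskArray", "BinaryMask", function(x) x@mask)

#' @describeIn probArray probability accessor
setMethod("probArray", "ProbabilityVolume", function(x) x@probs)

#' @describeIn spacing spacing accessor
setMethod("spacing", "Volume3D", function(x) x@spacing)

#' @describeIn nClasses for label volumes
setMethod("nClasses", "LabelVolume", function(x) x@nClasses)

#' @describeIn nClasses for probability volumes
setMethod("nClasses", "ProbabilityVolume", function(x) x@nClasses)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@mask))

#' @export
setMethod("dim", "ProbabilityVolume", function(x) dim(x@probs)[1:3])

.show_vol <- function(object, what, extra = "") {
  d <- dim(object)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm%s\n",
              what, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              extra))
}

setMethod("show", "CTVolume", function(object) {
  r <- range(object@voxels)
  .show_vol(object, "CTVolume",
            sprintf(", HU range [%.1f, %.1f]", r[1], r[2]))
})

setMethod("show", "LabelVolume", function(object) {
  nf <- sum(object@labels > 0L)
  .show_vol(object, "LabelVolume",
            sprintf(", N = %d classes, %d foreground voxels",
                    object@nClasses, nf))
})

setMethod("show", "BinaryMask", function(object) {
  .show_vol(object, "BinaryMask",
            sprintf(", %d foreground voxels", sum(object@mask)))
})

setMethod("show", "ProbabilityVolume", function(object) {
  .show_vol(object, "ProbabilityVolume",
            sprintf(", N = %d classes", object@nClasses))
})
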