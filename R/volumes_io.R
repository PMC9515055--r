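#' Read a volume from a NIfTI file
#'
#' Spacing and affine are taken from the NIfTI header.  For
#' \code{kind = "labels"} and \code{kind = "mask"} stored floating-point
#' values are rounded to the nearest integer; a value farther than 1e-3 from
#' an integer is an error, as is a label outside \code{[0, nClasses - 1]}.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param kind one of \code{"ct"}, \code{"labels"}, \code{"mask"}.
#' @param nClasses declared class count for \code{kind = "labels"};
#'   defaults to \code{max(labels) + 1}.
#' @return A \linkS4class{CTVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{BinaryMask} according to \code{kind}.
#' @export
readVolume <- function(path, kind = c("ct", "labels", "mask"),
                       nClasses = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (kind == "ct")
    return(new("CTVolume", voxels = arr * 1.0, spacing = sp, affine = aff))
  r <- round(arr)
  dev <- max(abs(arr - r))
  if (dev > 1e-3)
    stop(sprintf("stored values are not integral (max deviation %.3g > 1e-3)",
                 dev))
  storage.mode(r) <- "integer"
  if (kind == "mask") {
    if (!all(r == 0L | r == 1L))
      stop("mask values must be 0 or 1")
    return(new("BinaryMask", mask = r, spacing = sp, affine = aff))
  }
  if (is.null(nClasses)) nClasses <- max(r, 0L) + 1L
  if (any(r < 0L) || any(r > nClasses - 1L))
    stop(sprintf("label values outside [0, %d]", as.integer(nClasses) - 1L))
  new("LabelVolume", labels = r, nClasses = as.integer(nClasses),
      spacing = sp, affine = aff)
}

# float32 representability check via a 4-byte round trip
.is_float32_exact <- function(x) {
  v <- as.vector(x)
  idx <- seq_len(min(length(v), 100000L))
  back <- readBin(writeBin(v[idx], raw(), size = 4L), "double",
                  n = length(idx), size = 4L)
  if (!identical(back, v[idx])) return(FALSE)
  if (length(v) > length(idx)) {
    back <- readBin(writeBin(v, raw(), size = 4L), "double",
                    n = length(v), size = 4L)
    return(identical(back, v))
  }
  TRUE
}

#' Write a volume to a NIfTI file
#'
#' Output is gzip-compressed when \code{path} ends in \code{.gz}.  CT volumes
#' are stored as 32-bit float when every value is exactly representable
#' (true for generated phantoms, whose noise is quantised) and as 64-bit
#' float otherwise, so that \code{readVolume} always inverts
#' \code{writeVolume} voxelwise.  Labels and masks are stored as 16-bit
#' integers.
#'
#' @param volume a \linkS4class{CTVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{BinaryMask}.
#' @param path output path; the parent directory must exist.
#' @param datatype NIfTI storage type override (e.g. \code{"float"},
#'   \code{"double"}, \code{"int16"}); \code{NULL} selects as above.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, datatype = NULL) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (is(volume, "CTVolume")) {
    arr <- volume@voxels
    if (is.null(datatype))
      datatype <- if (.is_float32_exact(arr)) "float" else "double"
  } else if (is(volume, "LabelVolume")) {
    arr <- volume@labels * 1.0
    if (is.null(datatype)) datatype <- "int16"
  } else if (is(volume, "BinaryMask")) {
    arr <- volume@mask * 1.0
    if (is.null(datatype)) datatype <- "int16"
  } else stop("unsupported volume class: ", class(volume))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Map output voxel-centre index i (0-based) to input voxel coordinates for a
# spacing change; identical spacing maps to exactly i.
.src_coords <- function(nOut, spacingIn, spacingOut) {
  (seq_len(nOut) - 0.5) * (spacingOut / spacingIn) - 0.5
}

.resample_shape <- function(d, spacingIn, spacingOut) {
  out <- floor(d * spacingIn / spacingOut + 0.5)
  pmax(as.integer(out), 1L)
}

# nearest-neighbour index with half-ties rounded toward the origin
.nn_index <- function(s, n) {
  i <- ceiling(s - 0.5)
  pmin(pmax(i, 0), n - 1) + 1L
}

.resample_nn <- function(arr, spacingIn, spacingOut) {
  d <- dim(arr)
  nd <- .resample_shape(d, spacingIn, spacingOut)
  ix <- .nn_index(.src_coords(nd[1], spacingIn[1], spacingOut[1]), d[1])
  iy <- .nn_index(.src_coords(nd[2], spacingIn[2], spacingOut[2]), d[2])
  iz <- .nn_index(.src_coords(nd[3], spacingIn[3], spacingOut[3]), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

# separable trilinear interpolation, one axis at a time
.interp_axis1 <- function(arr, s) {
  d <- dim(arr)
  i0 <- pmin(pmax(floor(s), 0), d[1] - 1)
  f <- pmin(pmax(s - i0, 0), 1)
  i1 <- pmin(i0 + 1, d[1] - 1)
  a0 <- arr[i0 + 1, , , drop = FALSE]
  a1 <- arr[i1 + 1, , , drop = FALSE]
  out <- a0 * rep(1 - f, times = d[2] * d[3]) + a1 * rep(f, times = d[2] * d[3])
  array(out, c(length(s), d[2], d[3]))
}

.resample_tri <- function(arr, spacingIn, spacingOut) {
  d <- dim(arr)
  nd <- .resample_shape(d, spacingIn, spacingOut)
  out <- .interp_axis1(arr, .src_coords(nd[1], spacingIn[1], spacingOut[1]))
  out <- aperm(out, c(2, 1, 3))
  out <- .interp_axis1(out, .src_coords(nd[2], spacingIn[2], spacingOut[2]))
  out <- aperm(out, c(3, 2, 1))  # now (z, x, y)
  out <- .interp_axis1(out, .src_coords(nd[3], spacingIn[3], spacingOut[3]))
  aperm(out, c(2, 3, 1))
}

.check_target_spacing <- function(targetSpacing) {
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  if (length(targetSpacing) != 3L || any(!is.finite(targetSpacing)) ||
      any(targetSpacing <= 0))
    stop("'targetSpacing' must be three positive values (mm)")
  as.numeric(targetSpacing)
}

.resampled_affine <- function(affine, spacingIn, spacingOut) {
  s <- spacingOut / spacingIn
  affine[, 1:3] <- sweep(affine[, 1:3, drop = FALSE], 2, s, `*`)
  affine
}

#' @describeIn resampleVolume trilinear interpolation of HU values
setMethod("resampleVolume", "CTVolume", function(x, targetSpacing) {
  ts <- .check_target_spacing(targetSpacing)
  new("CTVolume", voxels = .resample_tri(x@voxels, x@spacing, ts),
      spacing = ts, affine = .resampled_affine(x@affine, x@spacing, ts))
})

#' @describeIn resampleVolume nearest-neighbour label transfer
setMethod("resampleVolume", "LabelVolume", function(x, targetSpacing) {
  ts <- .check_target_spacing(targetSpacing)
  new("LabelVolume", labels = .resample_nn(x@labels, x@spacing, ts),
      nClasses = x@nClasses, spacing = ts,
      affine = .resampled_affine(x@affine, x@spacing, ts))
})

#' @describeIn resampleVolume nearest-neighbour mask transfer
setMethod("resampleVolume", "BinaryMask", function(x, targetSpacing) {
  ts <- .check_target_spacing(targetSpacing)
  new("BinaryMask", mask = .resample_nn(x@mask, x@spacing, ts),
      spacing = ts, affine = .resampled_affine(x@affine, x@spacing, ts))
})

#' Collapse a multi-class segmentation to a binary bone-tissue mask
#'
#' The mask is 1 exactly where the label is nonzero.  Applied to a
#' ground-truth segmentation this yields the ground-truth bone-tissue mask
#' used for the upper-bound flavour of BEM inference.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @return A \linkS4class{BinaryMask} on the same grid.
#' @export
binarizeLabels <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  m <- (labels@labels > 0L) + 0L
  dim(m) <- dim(labels@labels)
  new("BinaryMask", mask = m, spacing = labels@spacing,
      affine = labels@affine)
}
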