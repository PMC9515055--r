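#' Sliding-window patch specification
#'
#' Defaults follow the reference inference protocol: 64^3 patches, scans
#' padded by 20 voxels on all sides, and a 20-voxel overlap between
#' neighbouring windows.
#'
#' @param patchSize window edge length in voxels.
#' @param overlap overlap between neighbouring windows, \code{0 <= overlap <
#'   patchSize}.
#' @param pad padding added around the scan before tiling, in voxels.
#' @param padValue HU fill value for the padding (air).
#' @return A validated list of class \code{PatchSpec}.
#' @export
patchSpec <- function(patchSize = 64L, overlap = 20L, pad = 20L,
                      padValue = -1024) {
  patchSize <- as.integer(patchSize)
  overlap <- as.integer(overlap)
  pad <- as.integer(pad)
  if (overlap < 0L || overlap >= patchSize)
    stop("need 0 <= overlap < patchSize")
  if (pad < 0L) stop("'pad' must be non-negative")
  structure(list(patchSize = patchSize, overlap = overlap, pad = pad,
                 padValue = padValue), class = "PatchSpec")
}

.tile_starts <- function(extent, patch, stride) {
  if (extent < patch) stop("padded volume smaller than one patch")
  s <- seq.int(1L, extent - patch + 1L, by = stride)
  if (s[length(s)] != extent - patch + 1L) s <- c(s, extent - patch + 1L)
  s
}

#' Assemble a whole-volume probability map patchwise
#'
#' Pads the CT by \code{spec$pad} voxels of \code{spec$padValue}, tiles it
#' with stride \code{patchSize - overlap} (the last window per axis is
#' shifted flush with the volume end), runs the model on each window, and
#' averages the per-voxel softmax probabilities of overlapping windows with
#' uniform weights before cropping back to the original shape.
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param model a \linkS4class{UNet3D}.
#' @param spec a \code{\link{patchSpec}}.
#' @return For the baseline a \linkS4class{ProbabilityVolume}; for dual-head
#'   variants a list with elements \code{multi} and \code{binary}.
#' @export
slidingWindowPredict <- function(ct, model, spec = patchSpec()) {
  stopifnot(is(ct, "CTVolume"), is(model, "UNet3D"),
            inherits(spec, "PatchSpec"))
  d <- dim(ct)
  pd <- d + 2L * spec$pad
  vol <- array(spec$padValue, pd)
  vol[spec$pad + seq_len(d[1]), spec$pad + seq_len(d[2]),
      spec$pad + seq_len(d[3])] <- ct@voxels
  ps <- spec$patchSize
  stride <- ps - spec$overlap
  sx <- .tile_starts(pd[1], ps, stride)
  sy <- .tile_starts(pd[2], ps, stride)
  sz <- .tile_starts(pd[3], ps, stride)
  C <- model@config$nClassesMulti
  dual <- model@config$variant != "baseline"
  accM <- array(0, c(C, pd))
  accB <- if (dual) array(0, c(2L, pd)) else NULL
  cnt <- array(0, pd)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    ix <- x0:(x0 + ps - 1L); iy <- y0:(y0 + ps - 1L); iz <- z0:(z0 + ps - 1L)
    x <- vol[ix, iy, iz]
    dim(x) <- c(1L, ps, ps, ps)
    fw <- .net_forward(model, x, cache = FALSE)
    pm <- .softmax_cv(fw$multi)
    dim(pm) <- c(C, ps, ps, ps)
    accM[, ix, iy, iz] <- accM[, ix, iy, iz] + pm
    if (dual) {
      pb <- .softmax_cv(fw$binary)
      dim(pb) <- c(2L, ps, ps, ps)
      accB[, ix, iy, iz] <- accB[, ix, iy, iz] + pb
    }
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  crop <- function(acc, nc) {
    a <- acc[, spec$pad + seq_len(d[1]), spec$pad + seq_len(d[2]),
             spec$pad + seq_len(d[3]), drop = FALSE]
    k <- cnt[spec$pad + seq_len(d[1]), spec$pad + seq_len(d[2]),
             spec$pad + seq_len(d[3])]
    a <- a / rep(k, each = nc)
    aperm(a, c(2, 3, 4, 1))
  }
  multi <- ProbabilityVolume(crop(accM, C), spacing = ct@spacing,
                             affine = ct@affine)
  if (!dual) return(multi)
  list(multi = multi,
       binary = ProbabilityVolume(crop(accB, 2L), spacing = ct@spacing,
                                  affine = ct@affine))
}

#' Standard argmax inference
#'
#' Per-voxel argmax over all N classes including background; ties break
#' toward the lowest class index.
#'
#' @param P a \linkS4class{ProbabilityVolume}.
#' @return A \linkS4class{LabelVolume}.
#' @export
standardArgmax <- function(P) {
  stopifnot(is(P, "ProbabilityVolume"))
  d <- dim(P@probs)
  m <- matrix(P@probs, nrow = prod(d[1:3]))
  lab <- max.col(m, ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  new("LabelVolume", labels = lab, nClasses = P@nClasses,
      spacing = P@spacing, affine = P@affine)
}

#' Binary-prediction-enhanced multi-class (BEM) inference
#'
#' The binary bone-tissue mask decides between background and bone: a voxel
#' with mask 0 becomes background; a voxel with mask 1 is assigned the most
#' probable \emph{foreground} class (argmax over classes 1..N-1, background
#' ignored, ties toward the lowest class index).  The output is therefore
#' nonzero exactly where the mask is 1, which corrects both false-negative
#' and false-positive background decisions of the standard argmax.
#'
#' @param P a \linkS4class{ProbabilityVolume} with N >= 2 classes.
#' @param B a \linkS4class{BinaryMask} on the same grid.
#' @return A \linkS4class{LabelVolume}.
#' @export
bemCombine <- function(P, B) {
  stopifnot(is(P, "ProbabilityVolume"), is(B, "BinaryMask"))
  d <- dim(P@probs)
  if (!all(d[1:3] == dim(B@mask))) stop("probability and mask shapes disagree")
  if (P@nClasses < 2L) stop("need at least one foreground class")
  m <- matrix(P@probs, nrow = prod(d[1:3]))
  fg <- max.col(m[, -1L, drop = FALSE], ties.method = "first")
  lab <- ifelse(as.vector(B@mask) == 1L, fg, 0L)
  lab <- as.integer(lab)
  dim(lab) <- d[1:3]
  new("LabelVolume", labels = lab, nClasses = P@nClasses,
      spacing = P@spacing, affine = P@affine)
}

#' Binarise a two-class probability volume
#'
#' The mask is 1 where the bone-tissue probability is greater than or equal
#' to the background probability (agreeing with \code{standardArgmax} up to
#' the tie, which goes to bone).
#'
#' @param P a \linkS4class{ProbabilityVolume} with exactly 2 classes.
#' @return A \linkS4class{BinaryMask}.
#' @export
maskToBinary <- function(P) {
  stopifnot(is(P, "ProbabilityVolume"))
  if (P@nClasses != 2L) stop("'P' must have exactly 2 classes")
  m <- (P@probs[, , , 2L] >= P@probs[, , , 1L]) + 0L
  dim(m) <- dim(P@probs)[1:3]
  new("BinaryMask", mask = m, spacing = P@spacing, affine = P@affine)
}
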