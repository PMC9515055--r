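# Evaluation metrics: per-class Sorensen-Dice, percentile summaries over
# detected classes, and (row-normalised) label confusion matrices.

.joint_counts <- function(pred, gt, N) {
  # N x N matrix, rows = ground-truth class, cols = predicted class
  code <- as.vector(gt) * N + as.vector(pred) + 1L
  m <- tabulate(code, nbins = N * N)
  matrix(m, nrow = N, byrow = TRUE)
}

#' Per-class Sorensen-Dice coefficients
#'
#' \code{DSC_c = 2 |X_c \& Y_c| / (|X_c| + |Y_c|)} between the predicted
#' voxel set X_c and the ground-truth voxel set Y_c of every foreground
#' class c.  Classes absent from both volumes get \code{NA} and are flagged
#' not present; the background class is excluded.
#'
#' @param pred predicted \linkS4class{LabelVolume}.
#' @param gt ground-truth \linkS4class{LabelVolume} on the same grid with
#'   the same class universe.
#' @return data.frame with one row per foreground class: \code{class},
#'   \code{dsc}, \code{hasTruePositive}, \code{presentInGt},
#'   \code{predVoxels}, \code{gtVoxels}.
#' @export
dscPerClass <- function(pred, gt) {
  stopifnot(is(pred, "LabelVolume"), is(gt, "LabelVolume"))
  if (!all(dim(pred) == dim(gt))) stop("prediction and gt shapes disagree")
  N <- max(pred@nClasses, gt@nClasses)
  cm <- .joint_counts(pred@labels, gt@labels, N)
  cls <- seq_len(N - 1L)
  tp <- diag(cm)[cls + 1L]
  nPred <- colSums(cm)[cls + 1L]
  nGt <- rowSums(cm)[cls + 1L]
  dsc <- ifelse(nPred + nGt > 0, 2 * tp / (nPred + nGt), NA_real_)
  data.frame(class = cls, dsc = dsc, hasTruePositive = tp > 0,
             presentInGt = nGt > 0, predVoxels = nPred, gtVoxels = nGt)
}

#' Summarise per-class Dice scores
#'
#' Median and 16-/84-percentiles (~1 sigma, linear interpolation between
#' order statistics) are computed over the classes with at least one
#' true-positive voxel; the detected fraction is the share of classes
#' present in the ground truth that reach \code{DSC > 0}.
#'
#' @param scores data.frame from \code{\link{dscPerClass}} (rows of several
#'   volumes may be concatenated).
#' @return list of class \code{SummaryStats}: \code{median}, \code{p16},
#'   \code{p84}, \code{detectedFraction}, \code{nDetected}, \code{nPresent}.
#' @export
summarizeScores <- function(scores) {
  present <- scores[scores$presentInGt | scores$predVoxels > 0, , drop = FALSE]
  inGt <- scores[scores$presentInGt, , drop = FALSE]
  if (nrow(inGt) == 0L) stop("no classes present in the ground truth")
  det <- present[present$hasTruePositive, , drop = FALSE]
  if (nrow(det) == 0L)
    stop("no class has a true-positive voxel; summary undefined")
  q <- stats::quantile(det$dsc, c(0.16, 0.5, 0.84), names = FALSE, type = 7)
  structure(list(median = q[2], p16 = q[1], p84 = q[3],
                 detectedFraction = sum(inGt$dsc > 0, na.rm = TRUE) / nrow(inGt),
                 nDetected = nrow(det), nPresent = nrow(inGt)),
            class = "SummaryStats")
}

#' Format summary statistics in median_{-s}^{+s}, (fraction) notation
#'
#' @param s a \code{SummaryStats} object from \code{\link{summarizeScores}}.
#' @param digits digits for the DSC values.
#' @return character(1), e.g. \code{"0.85_{-0.24}^{+0.08}, (0.94)"}.
#' @export
formatSummary <- function(s, digits = 2) {
  sprintf("%.*f_{-%.*f}^{+%.*f}, (%.2f)", digits, s$median, digits,
          s$median - s$p16, digits, s$p84 - s$median, s$detectedFraction)
}

#' Label confusion matrix
#'
#' Entry (i, j) counts voxels with ground-truth class i - 1 and predicted
#' class j - 1.  With \code{normalize = TRUE} every nonempty row is divided
#' by its sum (per-ground-truth-class recall profiles); rows of classes
#' absent from the ground truth stay all zero.
#'
#' @param pred predicted \linkS4class{LabelVolume}.
#' @param gt ground-truth \linkS4class{LabelVolume} on the same grid.
#' @param normalize divide rows by their sums.
#' @return N x N numeric matrix.
#' @export
confusionMatrixVolumes <- function(pred, gt, normalize = FALSE) {
  stopifnot(is(pred, "LabelVolume"), is(gt, "LabelVolume"))
  if (!all(dim(pred) == dim(gt))) stop("prediction and gt shapes disagree")
  N <- max(pred@nClasses, gt@nClasses)
  cm <- .joint_counts(pred@labels, gt@labels, N)
  if (normalize) {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm <- cm / ifelse(rs > 0, rs, 1)
  }
  dimnames(cm) <- list(gt = 0:(N - 1), pred = 0:(N - 1))
  cm
}

#' Most frequent off-diagonal confusions
#'
#' Ranks the off-diagonal entries of a (normalised) confusion matrix in
#' decreasing order; useful for choosing confusion sets for
#' \code{\link{correctLabels}} from a validation run.
#'
#' @param matrix confusion matrix, typically row-normalised.
#' @param topK number of pairs to return.
#' @return data.frame with columns \code{gtClass}, \code{predClass},
#'   \code{rate}, sorted by decreasing rate.
#' @export
confusionReport <- function(matrix, topK = 20L) {
  N <- nrow(matrix)
  idx <- which(row(matrix) != col(matrix) & matrix > 0)
  if (length(idx) == 0L)
    return(data.frame(gtClass = integer(0), predClass = integer(0),
                      rate = numeric(0)))
  df <- data.frame(gtClass = (idx - 1L) %% N,
                   predClass = (idx - 1L) %/% N,
                   rate = matrix[idx])
  df <- df[order(-df$rate, df$gtClass, df$predClass), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, topK)
}

#' Plot a confusion matrix heat map
#'
#' @param matrix confusion matrix (preferably row-normalised).
#' @param main plot title.
#' @return invisibly, NULL; draws on the active device.
#' @export
plotConfusionMatrix <- function(matrix, main = "Label confusion") {
  N <- nrow(matrix)
  graphics::image(0:(N) - 0.5, 0:(N) - 0.5, t(matrix[N:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "predicted class", ylab = "ground-truth class",
                  main = main, axes = FALSE, useRaster = TRUE)
  graphics::axis(1); graphics::axis(2)
  invisible(NULL)
}
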