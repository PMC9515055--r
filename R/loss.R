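# Combined segmentation loss: voxel-mean cross-entropy plus the sum over
# all classes of the per-class soft Dice loss, evaluated on softmax
# probabilities.  For dual-head models the same combination is added for
# the binary background/bone-tissue task, with the binary target derived
# on the fly from the multi-class ground truth.

# softmax over the channel (first) dimension; returns C x V matrix
.softmax_cv <- function(logits) {
  d <- dim(logits)
  C <- d[1]
  m <- matrix(logits, nrow = C)
  mx <- m[1, ]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, m[c, ])
  e <- exp(sweep(m, 2, mx))
  sweep(e, 2, colSums(e), `/`)
}

# cross-entropy + sum-over-classes soft Dice for one head.
# logits: (C, X, Y, Z); target: integer vector/array with values 0..C-1.
# Returns loss value and, if grad = TRUE, the gradient w.r.t. the logits.
.ce_dice_loss <- function(logits, target, smooth = 1e-5, grad = FALSE) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  d <- dim(logits)
  C <- d[1]
  V <- prod(d[2:4])
  tv <- as.integer(target)
  if (length(tv) != V) stop("logits and target shapes disagree")
  P <- .softmax_cv(logits)
  pTrue <- P[tv + 1L + C * (seq_len(V) - 1L)]
  ce <- -mean(log(pmax(pTrue, 1e-300)))
  Sg <- tabulate(tv + 1L, nbins = C)            # |G_c|
  Spg <- numeric(C)                              # sum_v p_cv g_cv
  agg <- rowsum(t(P), tv)                        # per observed class col-sums
  lev <- as.integer(rownames(agg))
  for (i in seq_along(lev)) Spg[lev[i] + 1L] <- agg[i, lev[i] + 1L]
  Sp <- rowSums(P)
  D <- Sp + Sg + smooth
  diceLoss <- sum(1 - (2 * Spg + smooth) / D)
  loss <- ce + diceLoss
  if (!grad) return(list(loss = loss, ce = ce, dice = diceLoss))
  # d(CE)/dlogits via the softmax shortcut: (P - G)/V
  G <- matrix(0, C, V)
  G[tv + 1L + C * (seq_len(V) - 1L)] <- 1
  gl <- (P - G) / V
  # d(Dice)/dp then through softmax
  A <- (2 * Spg + smooth) / (D * D)
  dLdp <- A - (2 / D) * G                        # C x V via recycling
  dot <- colSums(dLdp * P)
  gl <- gl + P * sweep(dLdp, 2, dot)
  dim(gl) <- d
  list(loss = loss, ce = ce, dice = diceLoss, grad = gl)
}

#' Combined cross-entropy and soft-Dice training loss
#'
#' Computes \code{L = CE(multi) + sum_c DiceLoss_c(multi)} and, when binary
#' logits are supplied (dual-head models), adds the same two terms for the
#' binary background/bone-tissue task whose target is
#' \code{binarizeLabels(gtLabels)}.  The per-class soft Dice loss is
#' \code{1 - (2 * sum(p g) + eps) / (sum(p) + sum(g) + eps)} on softmax
#' probabilities p and one-hot targets g; classes absent from both
#' prediction mass and target contribute 0 through the epsilon terms.
#'
#' @param multiLogits numeric array (C, X, Y, Z) of multi-class logits.
#' @param binaryLogits optional numeric array (2, X, Y, Z) of binary logits.
#' @param gtLabels \linkS4class{LabelVolume} patch (or integer array) of
#'   ground-truth labels.
#' @param smooth Dice smoothing epsilon.
#' @return Scalar loss value.
#' @export
combinedLoss <- function(multiLogits, binaryLogits = NULL, gtLabels,
                         smooth = 1e-5) {
  lab <- if (is(gtLabels, "LabelVolume")) gtLabels@labels else gtLabels
  if (!all(dim(multiLogits)[2:4] == dim(lab)))
    stop("logit and label spatial shapes disagree")
  total <- .ce_dice_loss(multiLogits, lab, smooth)$loss
  if (!is.null(binaryLogits)) {
    if (!all(dim(binaryLogits)[2:4] == dim(lab)))
      stop("binary logit and label spatial shapes disagree")
    total <- total + .ce_dice_loss(binaryLogits, (lab > 0L) + 0L, smooth)$loss
  }
  total
}
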