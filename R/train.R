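#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001,
#' 75000 single-patch iterations on 64^3-voxel patches, batch size fixed at
#' 1.  Desk-scale runs pass far fewer iterations and smaller patches.
#'
#' @param learningRate Adam step size.
#' @param iterations number of single-patch optimisation steps.
#' @param patchSize cubic patch edge length in voxels.
#' @param seed integer seed controlling patch sampling (and hence the whole
#'   optimisation trajectory).
#' @return A validated list of class \code{TrainConfig}; batch size is
#'   always 1.
#' @export
trainConfig <- function(learningRate = 0.001, iterations = 75000L,
                        patchSize = 64L, seed = 1L) {
  stopifnot(learningRate > 0, iterations >= 0, patchSize >= 2)
  structure(list(learningRate = learningRate,
                 iterations = as.integer(iterations), batchSize = 1L,
                 patchSize = as.integer(patchSize), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Sample a random training patch
#'
#' Draws an axis-aligned crop at a uniformly random valid origin; the CT and
#' label grids are cropped congruently.  Patchwise sampling doubles as the
#' only data augmentation (random cropping).
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param labels the matching \linkS4class{LabelVolume}.
#' @param size patch edge length (scalar or length-3).
#' @return list with elements \code{ct} and \code{labels}, both 3D arrays,
#'   and \code{origin} (1-based corner index).  Uses the current RNG stream.
#' @export
samplePatch <- function(ct, labels, size) {
  d <- dim(ct)
  if (!all(d == dim(labels))) stop("ct and labels shapes disagree")
  size <- rep(as.integer(size), length.out = 3L)
  if (any(size > d)) stop("volume smaller than the requested patch")
  origin <- vapply(1:3, function(a) sample.int(d[a] - size[a] + 1L, 1L), 0L)
  ix <- origin[1]:(origin[1] + size[1] - 1L)
  iy <- origin[2]:(origin[2] + size[2] - 1L)
  iz <- origin[3]:(origin[3] + size[3] - 1L)
  list(ct = voxels(ct)[ix, iy, iz, drop = FALSE],
       labels = labelArray(labels)[ix, iy, iz, drop = FALSE],
       origin = origin)
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }), t = 0L)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.load_training_volumes <- function(volumes) {
  if (is.data.frame(volumes)) {
    rows <- if ("split" %in% names(volumes))
      volumes[volumes$split == "train", , drop = FALSE] else volumes
    if (nrow(rows) == 0L) stop("manifest has an empty training split")
    lapply(seq_len(nrow(rows)), function(i)
      list(ct = readVolume(rows$ct[i], "ct"),
           labels = readVolume(rows$seg[i], "labels")))
  } else {
    if (length(volumes) == 0L) stop("empty training set")
    volumes
  }
}

#' Train a network with Adam on randomly sampled patches
#'
#' Runs \code{cfg$iterations} single-patch steps: a training volume is drawn
#' uniformly, a random patch is cropped from it, the combined
#' cross-entropy + soft-Dice loss (plus the binary terms for dual-head
#' variants) is backpropagated, and Adam updates the weights.  The run is
#' deterministic given \code{cfg$seed}.
#'
#' @param model a \linkS4class{UNet3D} (its \code{nClassesMulti} must cover
#'   the label range; use \code{nClassesMulti = 2} with binarised labels to
#'   train a separate binary network for the two-stage approach).
#' @param volumes either a manifest data.frame with columns \code{ct},
#'   \code{seg} and optionally \code{split} (rows with \code{split ==
#'   "train"} are used), or a list of \code{list(ct =, labels =)} volume
#'   pairs.
#' @param cfg a \code{\link{trainConfig}}.
#' @param binarizeTargets if TRUE the sampled label patches are collapsed to
#'   background/bone before the loss (train a 2-class network on the binary
#'   task).
#' @return list with the trained \code{model} and \code{trace}, a
#'   data.frame of per-iteration losses.
#' @export
trainNetwork <- function(model, volumes, cfg = trainConfig(),
                         binarizeTargets = FALSE) {
  stopifnot(is(model, "UNet3D"), inherits(cfg, "TrainConfig"))
  vols <- .load_training_volumes(volumes)
  dual <- model@config$variant != "baseline"
  params <- model@params
  state <- .adam_init(params)
  trace <- numeric(cfg$iterations)
  if (cfg$iterations > 0L) .run_with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      vi <- sample.int(length(vols), 1L)
      patch <- samplePatch(vols[[vi]]$ct, vols[[vi]]$labels, cfg$patchSize)
      lab <- patch$labels
      if (binarizeTargets) lab <- (lab > 0L) + 0L
      x <- patch$ct
      dim(x) <- c(1L, dim(patch$ct))
      modelIt <- new("UNet3D", config = model@config, params = params)
      fw <- .net_forward(modelIt, x, cache = TRUE)
      lm <- .ce_dice_loss(fw$multi, lab, grad = TRUE)
      loss <- lm$loss
      gBin <- NULL
      if (dual) {
        lb <- .ce_dice_loss(fw$binary, (lab > 0L) + 0L, grad = TRUE)
        loss <- loss + lb$loss
        gBin <- lb$grad
      }
      grads <- .net_backward(modelIt, fw, lm$grad, gBin)
      upd <- .adam_step(params, grads, state, cfg$learningRate)
      params <- upd$params
      state <- upd$state
      trace[it] <- loss
    }
  })
  list(model = new("UNet3D", config = model@config, params = params),
       trace = data.frame(iteration = seq_len(cfg$iterations), loss = trace))
}
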