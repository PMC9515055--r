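#' 3D U-Net trained end-to-end for distinct bone segmentation
#'
#' Holds the architecture configuration and the flat named list of trainable
#' parameter arrays for the baseline 3D U-Net or one of its four
#' dual-segmentation-head variants.
#'
#' @slot config list produced by \code{\link{networkConfig}}.
#' @slot params named list of numeric parameter arrays.
#' @export
setClass("UNet3D", representation(config = "list", params = "list"))

setMethod("show", "UNet3D", function(object) {
  cfg <- object@config
  cat(sprintf("UNet3D '%s': %d classes, %d levels, channels %s, %s trainable parameters\n",
              cfg$variant, cfg$nClassesMulti, cfg$levels,
              paste(cfg$channels, collapse = "-"),
              format(countParameters(object), big.mark = ",")))
})

#' Architecture configuration for the 3D U-Net family
#'
#' The default channel widths (32, 56, 96, 176, 448) are pinned so that the
#' closed-form trainable-parameter counts of the shipped architecture match
#' the reference accounting for the 126-class problem: 1.46e7 for the
#' baseline (and, to three significant figures, for Dual A, B and C) and
#' 1.98e7 for Dual D.
#'
#' @param variant \code{"baseline"} or one of \code{"dual_a"},
#'   \code{"dual_b"}, \code{"dual_c"}, \code{"dual_d"}: \describe{
#'   \item{dual_a}{shared trunk; two 1x1x1 classification heads.}
#'   \item{dual_b}{shared trunk; each head preceded by its own full-resolution
#'     convolutional block.}
#'   \item{dual_c}{binary head directly on the decoder output; the multi-class
#'     head after one additional full-resolution convolutional block.}
#'   \item{dual_d}{shared encoder and feature encoding; two separate
#'     decoders.}}
#' @param nClassesMulti class count C of the multi-class head (including
#'   background), at least 2.
#' @param levels number of resolution levels.
#' @param channels strictly increasing per-level channel widths.
#' @param leakySlope negative-region slope of the leaky ReLU.
#' @param normEpsilon epsilon of the instance normalisation.
#' @return A validated list of class \code{NetworkConfig}.
#' @export
networkConfig <- function(variant = c("baseline", "dual_a", "dual_b",
                                      "dual_c", "dual_d"),
                          nClassesMulti = 126L, levels = 5L,
                          channels = c(32L, 56L, 96L, 176L, 448L),
                          leakySlope = 0.01, normEpsilon = 1e-5) {
  variant <- match.arg(variant)
  channels <- as.integer(channels)
  if (length(channels) != levels)
    stop("'channels' must have one width per level")
  if (any(diff(channels) <= 0))
    stop("'channels' must be strictly increasing over encoder levels")
  if (nClassesMulti < 2L) stop("'nClassesMulti' must be at least 2")
  structure(list(variant = variant, nClassesMulti = as.integer(nClassesMulti),
                 levels = as.integer(levels), channels = channels,
                 leakySlope = leakySlope, normEpsilon = normEpsilon),
            class = "NetworkConfig")
}

.init_conv <- function(cin, cout, k, params, pfx) {
  n <- cout * cin * k^3
  w <- array(stats::rnorm(n, sd = sqrt(2 / (cin * k^3))),
             c(cout, cin, k, k, k))
  params[[paste0(pfx, ".w")]] <- w
  params[[paste0(pfx, ".b")]] <- numeric(cout)
  params
}

.init_unit <- function(cin, cout, k, params, pfx) {
  params <- .init_conv(cin, cout, k, params, pfx)
  params[[paste0(pfx, ".g")]] <- rep(1, cout)
  params[[paste0(pfx, ".nb")]] <- numeric(cout)
  params
}

.init_block <- function(cin, cout, params, pfx) {
  params <- .init_unit(cin, cout, 3L, params, paste0(pfx, ".c1"))
  .init_unit(cout, cout, 3L, params, paste0(pfx, ".c2"))
}

.init_decoder <- function(ch, params, pfx) {
  L <- length(ch)
  for (l in seq(L - 1, 1))
    params <- .init_block(ch[l + 1] + ch[l], ch[l], params,
                          sprintf("%s%d", pfx, l))
  params
}

#' Build a trainable network
#'
#' Allocates and initialises (He-normal weights, zero biases, unit norm
#' gains) all parameter arrays of the requested variant.  A built model maps
#' a 1-channel HU patch to a C-channel multi-class logit patch of equal
#' spatial size and, for the dual variants, additionally to a 2-channel
#' binary background/bone-tissue logit patch.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed for weight initialisation.
#' @return A \linkS4class{UNet3D}.
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  stopifnot(inherits(config, "NetworkConfig"))
  ch <- config$channels
  L <- config$levels
  C <- config$nClassesMulti
  .run_with_seed(seed, {
    params <- list()
    params <- .init_block(1L, ch[1], params, "enc1")
    for (l in 2:L)
      params <- .init_block(ch[l - 1], ch[l], params, sprintf("enc%d", l))
    params <- .init_decoder(ch, params, "dec")
    v <- config$variant
    if (v == "dual_d") params <- .init_decoder(ch, params, "binDec")
    if (v %in% c("dual_b", "dual_c"))
      params <- .init_unit(ch[1], ch[1], 3L, params, "multiBlock.c1")
    if (v == "dual_b")
      params <- .init_unit(ch[1], ch[1], 3L, params, "binBlock.c1")
    params <- .init_conv(ch[1], C, 1L, params, "multiHead")
    if (v != "baseline")
      params <- .init_conv(ch[1], 2L, 1L, params, "binHead")
    new("UNet3D", config = unclass(config), params = params)
  })
}

#' Count trainable parameters
#'
#' @param model a \linkS4class{UNet3D}.
#' @return Total number of trainable scalar parameters.
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "UNet3D"))
  sum(vapply(model@params, length, 0L))
}

# Forward pass.  x: (1, X, Y, Z) numeric array with spatial extents
# divisible by 2^(levels-1).  Returns multi-class logits, binary logits
# (NULL for the baseline) and, if cache = TRUE, everything backprop needs.
.net_forward <- function(model, x, cache = TRUE) {
  cfg <- model@config
  p <- model@params
  L <- cfg$levels
  d <- dim(x)[2:4]
  if (any(d %% 2^(L - 1) != 0))
    stop(sprintf("patch extents (%s) must be divisible by 2^(levels-1) = %d",
                 paste(d, collapse = "x"), 2^(L - 1)))
  skips <- vector("list", L)
  encCache <- vector("list", L)
  pools <- vector("list", L - 1)
  cur <- x
  for (l in 1:L) {
    blk <- .block_fwd(cur, p, sprintf("enc%d", l), cfg, cache)
    encCache[[l]] <- blk
    skips[[l]] <- blk$y
    if (l < L) {
      pl <- .cpp_maxpool2_fwd(blk$y, dim(blk$y))
      pools[[l]] <- pl$idx
      cur <- pl$y
    } else cur <- blk$y
  }
  runDecoder <- function(pfx) {
    dc <- vector("list", L - 1)
    xx <- cur
    for (l in seq(L - 1, 1)) {
      up <- .cpp_upsample_fwd(xx, dim(xx), dim(skips[[l]])[2:4])
      cat4 <- .cat_channels(up, skips[[l]])
      blk <- .block_fwd(cat4, p, sprintf("%s%d", pfx, l), cfg, cache)
      dc[[l]] <- list(block = blk, upDim = dim(xx), nUp = dim(up)[1])
      xx <- blk$y
    }
    list(y = xx, cache = dc)
  }
  dec <- runDecoder("dec")
  v <- cfg$variant
  binLogits <- NULL
  binDec <- NULL
  multiIn <- dec$y
  multiBlk <- NULL
  binBlk <- NULL
  if (v %in% c("dual_b", "dual_c")) {
    multiBlk <- .unit_fwd(dec$y, p, "multiBlock.c1", cfg, cache)
    multiIn <- multiBlk$y
  }
  multiLogits <- .head_fwd(multiIn, p, "multiHead")
  if (v == "dual_a") {
    binLogits <- .head_fwd(dec$y, p, "binHead")
  } else if (v == "dual_b") {
    binBlk <- .unit_fwd(dec$y, p, "binBlock.c1", cfg, cache)
    binLogits <- .head_fwd(binBlk$y, p, "binHead")
  } else if (v == "dual_c") {
    binLogits <- .head_fwd(dec$y, p, "binHead")
  } else if (v == "dual_d") {
    binDec <- runDecoder("binDec")
    binLogits <- .head_fwd(binDec$y, p, "binHead")
  }
  out <- list(multi = multiLogits, binary = binLogits)
  if (cache)
    out$cache <- list(x = x, enc = encCache, pools = pools, skips = skips,
                      dec = dec, binDec = binDec, multiBlk = multiBlk,
                      binBlk = binBlk, multiIn = multiIn)
  out
}

.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- numeric((da[1] + db[1]) * prod(da[2:4]))
  dim(out) <- c(da[1] + db[1], da[2:4])
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# Backward pass; gMulti/gBinary are gradients w.r.t. the logits.
# Returns the named gradient list aligned with model@params.
.net_backward <- function(model, fw, gMulti, gBinary = NULL) {
  cfg <- model@config
  p <- model@params
  L <- cfg$levels
  cc <- fw$cache
  grads <- lapply(p, function(z) { g <- z; g[] <- 0; g })
  v <- cfg$variant
  skipGrads <- vector("list", L)
  zeroLike <- function(a) { g <- a; g[] <- 0; g }

  decBackward <- function(pfx, decCache, gOut, grads) {
    gx <- gOut
    for (l in seq(1, L - 1)) {
      st <- decCache[[l]]
      bb <- .block_bwd(gx, st$block, p, sprintf("%s%d", pfx, l), cfg, grads)
      grads <- bb$grads
      nUp <- st$nUp
      gcat <- bb$gx
      gup <- gcat[seq_len(nUp), , , , drop = FALSE]
      dim(gup) <- c(nUp, dim(gcat)[2:4])
      gskip <- gcat[nUp + seq_len(dim(gcat)[1] - nUp), , , , drop = FALSE]
      dim(gskip) <- c(dim(gcat)[1] - nUp, dim(gcat)[2:4])
      skipGrads[[l]] <<- if (is.null(skipGrads[[l]])) gskip
                         else skipGrads[[l]] + gskip
      gx <- .cpp_upsample_bwd(gup, st$upDim, dim(gup)[2:4])
    }
    list(gBottleneck = gx, grads = grads)
  }

  # heads (and full-resolution extra blocks)
  hb <- .head_bwd(gMulti, cc$multiIn, p, "multiHead", grads)
  grads <- hb$grads
  gDecOut <- hb$gx
  if (v %in% c("dual_b", "dual_c")) {
    ub <- .unit_bwd(gDecOut, cc$multiBlk, p, "multiBlock.c1", cfg, grads)
    grads <- ub$grads
    gDecOut <- ub$gx
  }
  gBottleneck <- NULL
  if (v == "dual_a" || v == "dual_c") {
    hbB <- .head_bwd(gBinary, cc$dec$y, p, "binHead", grads)
    grads <- hbB$grads
    gDecOut <- gDecOut + hbB$gx
  } else if (v == "dual_b") {
    hbB <- .head_bwd(gBinary, cc$binBlk$y, p, "binHead", grads)
    grads <- hbB$grads
    ubB <- .unit_bwd(hbB$gx, cc$binBlk, p, "binBlock.c1", cfg, grads)
    grads <- ubB$grads
    gDecOut <- gDecOut + ubB$gx
  } else if (v == "dual_d") {
    hbB <- .head_bwd(gBinary, cc$binDec$y, p, "binHead", grads)
    grads <- hbB$grads
    db <- decBackward("binDec", cc$binDec$cache, hbB$gx, grads)
    grads <- db$grads
    gBottleneck <- db$gBottleneck
  }
  db <- decBackward("dec", cc$dec$cache, gDecOut, grads)
  grads <- db$grads
  gBottleneck <- if (is.null(gBottleneck)) db$gBottleneck
                 else gBottleneck + db$gBottleneck

  # encoder, deepest level first
  gcur <- gBottleneck
  for (l in seq(L, 1)) {
    if (l < L) {
      gcur <- .cpp_maxpool2_bwd(gcur, cc$pools[[l]], dim(cc$skips[[l]]))
      gcur <- gcur + skipGrads[[l]]
    }
    bb <- .block_bwd(gcur, cc$enc[[l]], p, sprintf("enc%d", l), cfg, grads)
    grads <- bb$grads
    gcur <- bb$gx
  }
  grads
}
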