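# Layer primitives for the 3D U-Net family.  Tensors are numeric arrays
# with dim (C, X, Y, Z); convolution and resampling kernels live in C++.

.conv_fwd <- function(x, w, b, k) .cpp_conv3d_fwd(x, dim(x), w, b, k)

.conv_bwd <- function(x, w, k, gy) .cpp_conv3d_bwd(x, dim(x), w, k, gy,
                                                  dim(w)[1])

.inorm_fwd <- function(x, g, b, eps) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- g * xhat + b
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv)
}

.inorm_bwd <- function(gy, cache, g) {
  d <- dim(gy)
  C <- d[1]
  gm <- matrix(gy, nrow = C)
  xhat <- cache$xhat
  V <- ncol(gm)
  dxhat <- gm * g
  gg <- rowSums(gm * xhat)
  gb <- rowSums(gm)
  gx <- (cache$inv / V) * (V * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(gx) <- d
  list(gx = gx, gg = gg, gb = gb)
}

.lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}

.lrelu_bwd <- function(gy, neg, slope) {
  g <- gy
  g[neg] <- slope * gy[neg]
  g
}

# conv -> instance norm -> leaky ReLU
.unit_fwd <- function(x, params, pfx, cfg, cache = TRUE) {
  w <- params[[paste0(pfx, ".w")]]
  k <- dim(w)[3]
  y <- .conv_fwd(x, w, params[[paste0(pfx, ".b")]], k)
  nrm <- .inorm_fwd(y, params[[paste0(pfx, ".g")]],
                    params[[paste0(pfx, ".nb")]], cfg$normEpsilon)
  act <- .lrelu_fwd(nrm$y, cfg$leakySlope)
  if (cache)
    list(y = act$y, x = x, k = k, norm = nrm[c("xhat", "inv")], neg = act$neg)
  else list(y = act$y)
}

.unit_bwd <- function(gy, cache, params, pfx, cfg, grads) {
  g <- .lrelu_bwd(gy, cache$neg, cfg$leakySlope)
  nb <- .inorm_bwd(g, cache$norm, params[[paste0(pfx, ".g")]])
  cb <- .conv_bwd(cache$x, params[[paste0(pfx, ".w")]], cache$k, nb$gx)
  grads[[paste0(pfx, ".g")]] <- grads[[paste0(pfx, ".g")]] + nb$gg
  grads[[paste0(pfx, ".nb")]] <- grads[[paste0(pfx, ".nb")]] + nb$gb
  grads[[paste0(pfx, ".w")]] <- grads[[paste0(pfx, ".w")]] + cb$gw
  grads[[paste0(pfx, ".b")]] <- grads[[paste0(pfx, ".b")]] + cb$gb
  list(gx = cb$gx, grads = grads)
}

# two conv units, the standard level block
.block_fwd <- function(x, params, pfx, cfg, cache = TRUE) {
  u1 <- .unit_fwd(x, params, paste0(pfx, ".c1"), cfg, cache)
  u2 <- .unit_fwd(u1$y, params, paste0(pfx, ".c2"), cfg, cache)
  list(y = u2$y, u1 = u1, u2 = u2)
}

.block_bwd <- function(gy, cache, params, pfx, cfg, grads) {
  b2 <- .unit_bwd(gy, cache$u2, params, paste0(pfx, ".c2"), cfg, grads)
  grads <- b2$grads
  b1 <- .unit_bwd(b2$gx, cache$u1, params, paste0(pfx, ".c1"), cfg, grads)
  list(gx = b1$gx, grads = b1$grads)
}

.head_fwd <- function(x, params, pfx)
  .conv_fwd(x, params[[paste0(pfx, ".w")]], params[[paste0(pfx, ".b")]], 1L)

.head_bwd <- function(gy, x, params, pfx, grads) {
  cb <- .conv_bwd(x, params[[paste0(pfx, ".w")]], 1L, gy)
  grads[[paste0(pfx, ".w")]] <- grads[[paste0(pfx, ".w")]] + cb$gw
  grads[[paste0(pfx, ".b")]] <- grads[[paste0(pfx, ".b")]] + cb$gb
  list(gx = cb$gx, grads = grads)
}
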