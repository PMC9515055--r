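# 3D convex hulls of voxel point sets, used to build the soft-tissue body
# silhouette of the synthetic phantom.  The hull is computed exactly on a
# reduced point set: for every axis-aligned column of voxels only the two
# extreme voxels are kept.  Every vertex of the convex hull maximises some
# linear functional and is therefore extreme within its column along any
# axis on which that functional has a nonzero component, so the reduction
# loses no hull vertex.

.column_extremes <- function(coords) {
  keep <- logical(nrow(coords))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- paste(coords[, others[1]], coords[, others[2]])
    o <- order(key, coords[, ax])
    first <- !duplicated(key[o])
    last <- !duplicated(key[o], fromLast = TRUE)
    keep[o[first | last]] <- TRUE
  }
  coords[keep, , drop = FALSE]
}

# plane through rows p1, p2, p3 oriented so `inside` satisfies n.x < d;
# returns c(n, d) with unit normal
.facet_plane <- function(p1, p2, p3, inside) {
  u <- p2 - p1; v <- p3 - p1
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0) return(NULL)
  n <- n / nn
  d <- sum(n * p1)
  if (sum(n * inside) > d) { n <- -n; d <- -d }
  c(n, d)
}

# Quickhull-style incremental convex hull of an n x 3 point matrix.
# Returns NULL for degenerate (rank < 3) input, otherwise
# list(normals = F x 3 unit normals, offsets = length F) with the hull as
# the half-space intersection normals %*% x <= offsets.
.convex_hull3d <- function(pts, eps = 1e-9) {
  pts <- unique(pts)
  if (nrow(pts) < 4) return(NULL)
  tol <- eps * (max(abs(pts)) + 1)
  # initial simplex from spread-out extreme points
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < tol) return(NULL)
  v <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(w[, 2] * v[3] - w[, 3] * v[2],
              w[, 3] * v[1] - w[, 1] * v[3],
              w[, 1] * v[2] - w[, 2] * v[1])
  dl <- rowSums(cr^2)
  i3 <- which.max(dl)
  if (dl[i3] < tol^2) return(NULL)
  pl <- .facet_plane(pts[i1, ], pts[i2, ], pts[i3, ], pts[i1, ])
  h <- as.vector(pts %*% pl[1:3]) - pl[4]
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < tol) return(NULL)
  simplex <- c(i1, i2, i3, i4)
  centroid <- colMeans(pts[simplex, ])
  tri <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  verts <- matrix(simplex[t(tri)], ncol = 3, byrow = TRUE)
  planes <- t(apply(verts, 1, function(vv)
    .facet_plane(pts[vv[1], ], pts[vv[2], ], pts[vv[3], ], centroid)))
  insert <- function(p) {
    s <- as.vector(planes[, 1:3, drop = FALSE] %*% pts[p, ]) - planes[, 4]
    vis <- which(s > tol)
    if (length(vis) == 0) return(FALSE)
    ev <- verts[vis, , drop = FALSE]
    edges <- rbind(ev[, c(1, 2), drop = FALSE], ev[, c(2, 3), drop = FALSE],
                   ev[, c(3, 1), drop = FALSE])
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1)), ,
                     drop = FALSE]
    newV <- cbind(horizon, p)
    newP <- t(apply(newV, 1, function(vv)
      .facet_plane(pts[vv[1], ], pts[vv[2], ], pts[vv[3], ], centroid)))
    ok <- !vapply(seq_len(nrow(newP)), function(i) any(is.na(newP[i, ])),
                  TRUE)
    verts <<- rbind(verts[-vis, , drop = FALSE], newV[ok, , drop = FALSE])
    planes <<- rbind(planes[-vis, , drop = FALSE], newP[ok, , drop = FALSE])
    TRUE
  }
  cand <- setdiff(seq_len(nrow(pts)), simplex)
  repeat {
    if (length(cand) == 0) break
    S <- planes[, 1:3, drop = FALSE] %*% t(pts[cand, , drop = FALSE]) -
      planes[, 4]
    mx <- do.call(pmax, c(asplit(S, 1), list(na.rm = TRUE)))
    keep <- mx > tol
    cand <- cand[keep]
    if (length(cand) == 0) break
    mx <- mx[keep]
    p <- cand[which.max(mx)]
    insert(p)
    cand <- setdiff(cand, p)
  }
  list(normals = planes[, 1:3, drop = FALSE], offsets = planes[, 4])
}

# Rasterise a half-space intersection into voxel coordinates by scanning
# x-rows: for every (y, z) the facet inequalities reduce to an interval of
# admissible x.  Returns an n x 3 integer-valued coordinate matrix.
.rasterize_hull <- function(hull, lo, hi, tol = 1e-6) {
  ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  m <- length(ys) * length(zs)
  Y <- rep(ys, times = length(zs))
  Z <- rep(zs, each = length(ys))
  xlo <- rep(lo[1], m); xhi <- rep(hi[1], m)
  feas <- rep(TRUE, m)
  for (f in seq_len(nrow(hull$normals))) {
    n <- hull$normals[f, ]
    r <- hull$offsets[f] + tol - n[2] * Y - n[3] * Z
    if (n[1] > 1e-12) {
      xhi <- pmin(xhi, floor(r / n[1] + 1e-9))
    } else if (n[1] < -1e-12) {
      xlo <- pmax(xlo, ceiling(r / n[1] - 1e-9))
    } else {
      feas <- feas & (r >= 0)
    }
  }
  cnt <- xhi - xlo + 1
  sel <- feas & cnt > 0
  if (!any(sel)) return(matrix(0L, 0, 3))
  cnt <- cnt[sel]
  cbind(sequence(cnt, from = xlo[sel], by = 1),
        rep(Y[sel], times = cnt),
        rep(Z[sel], times = cnt))
}

# Logical mask (shape dm) of the convex hull of integer voxel coordinates
# (n x 3, 1-based).  Degenerate (flat) point sets fall back to the points
# themselves; the generators are always contained.
.convex_mask <- function(coords, dm) {
  out <- array(FALSE, dm)
  if (nrow(coords) == 0) return(out)
  red <- .column_extremes(unique(coords))
  hull <- .convex_hull3d(red)
  if (!is.null(hull)) {
    lo <- pmax(apply(coords, 2, min), 1L)
    hi <- pmin(apply(coords, 2, max), dm)
    vox <- .rasterize_hull(hull, lo, hi)
    vox <- vox[vox[, 1] >= 1 & vox[, 1] <= dm[1], , drop = FALSE]
    out[vox] <- TRUE
  }
  out[coords] <- TRUE
  out
}
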