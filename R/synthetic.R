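# Procedural synthetic skeletal CT phantoms.
#
# The generator rasterises a randomised stick-figure skeleton of 41 distinct
# bones into a label volume, wraps the bones of each body compartment (head,
# torso, arms, legs) in its convex hull to form a soft-tissue silhouette,
# and renders a CT by filling background / soft tissue / cancellous /
# cortical regimes with typical HU values plus i.i.d. uniform noise.  Bones
# within a family (vertebrae, ribs, long bones) share their geometry and
# differ chiefly in position, which forces a segmentation model to use
# relative position, not shape alone, to tell them apart.

.run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Reference skeleton, coordinates in a 128 x 128 x 256 frame (z = head-foot
# axis).  Families: sphere, disc (squashed cylinder along z), rod (capsule),
# tube (capsule swept along an arc), box.
.reference_inventory <- function() {
  bones <- list()
  add <- function(label, family, compartment, geom)
    bones[[length(bones) + 1]] <<- c(list(label = label, family = family,
                                          compartment = compartment), geom)
  add(1L, "sphere", "head", list(center = c(64, 74, 236), r = 11))
  for (k in 0:11)                                  # vertebral column
    add(2L + k, "disc", "torso",
        list(center = c(64, 74, 130 + 8 * k), r = 6.5, h = 2.8))
  rib_arc <- function(side, z) {
    th <- seq(8, 145, by = 3) * pi / 180
    droop <- seq(0, -5, length.out = length(th))
    cbind(64 + side * 26 * sin(th), 58 + 22 * cos(th), z + droop)
  }
  for (k in 0:7) {                                 # 8 rib pairs
    z <- 158 + 8 * k
    add(14L + 2L * k, "tube", "torso", list(pts = rib_arc(-1, z), r = 1.8))
    add(15L + 2L * k, "tube", "torso", list(pts = rib_arc(+1, z), r = 1.8))
  }
  mirror <- function(p) { p[1] <- 128 - p[1]; p }
  add(30L, "rod", "torso", list(p0 = c(58, 56, 221), p1 = c(40, 52, 219), r = 2))
  add(31L, "rod", "torso", list(p0 = mirror(c(58, 56, 221)),
                                p1 = mirror(c(40, 52, 219)), r = 2))
  add(32L, "rod", "arm_left", list(p0 = c(39, 52, 216), p1 = c(34, 54, 184), r = 2.8))
  add(33L, "rod", "arm_left", list(p0 = c(34, 54, 181), p1 = c(31, 56, 150), r = 2.2))
  add(34L, "rod", "arm_right", list(p0 = mirror(c(39, 52, 216)),
                                    p1 = mirror(c(34, 54, 184)), r = 2.8))
  add(35L, "rod", "arm_right", list(p0 = mirror(c(34, 54, 181)),
                                    p1 = mirror(c(31, 56, 150)), r = 2.2))
  add(36L, "box", "torso", list(center = c(64, 64, 120), half = c(15, 7, 7)))
  add(37L, "rod", "leg_left", list(p0 = c(55, 64, 112), p1 = c(51, 64, 62), r = 3.2))
  add(38L, "rod", "leg_left", list(p0 = c(51, 64, 58), p1 = c(50, 64, 12), r = 2.6))
  add(39L, "rod", "leg_right", list(p0 = mirror(c(55, 64, 112)),
                                    p1 = mirror(c(51, 64, 62)), r = 3.2))
  add(40L, "rod", "leg_right", list(p0 = mirror(c(51, 64, 58)),
                                    p1 = mirror(c(50, 64, 12)), r = 2.6))
  add(41L, "box", "torso", list(center = c(64, 36, 186), half = c(3.5, 2, 16)))
  bones
}

#' Parameters of the synthetic skeleton generator
#'
#' @param volumeShape integer(3) grid shape; the default reproduces the
#'   published phantom geometry of 128 x 128 x 256 voxels.
#' @param jitterTranslate half-range, in reference voxels, of the uniform
#'   random per-bone translation.
#' @param jitterScale half-range of the uniform random per-bone relative
#'   scale perturbation (0.05 = +-5\%).
#' @param jitterRotate half-range, in degrees, of the random rotation about
#'   the z and y axes applied to rod- and tube-shaped bones.
#' @param seed integer seed fixing the whole skeleton.
#' @param retryBudget attempts per bone to find a jitter that keeps the bone
#'   inside the volume before failing.
#' @return An object of class \code{AnatomyParams} (a validated list) with
#'   the 41-bone inventory attached.
#' @export
anatomyParams <- function(volumeShape = c(128L, 128L, 256L),
                          jitterTranslate = 2, jitterScale = 0.05,
                          jitterRotate = 3, seed = 1L, retryBudget = 25L) {
  volumeShape <- as.integer(volumeShape)
  stopifnot(length(volumeShape) == 3L, all(volumeShape >= 8L))
  jit <- c(jitterTranslate, jitterScale, jitterRotate)
  if (any(!is.finite(jit)) || any(jit < 0))
    stop("jitter ranges must be finite and non-negative")
  inv <- .reference_inventory()
  stopifnot(length(inv) == 41L,
            identical(vapply(inv, `[[`, 0L, "label"), 1:41))
  structure(list(volumeShape = volumeShape, boneInventory = inv,
                 jitterTranslate = jitterTranslate,
                 jitterScale = jitterScale, jitterRotate = jitterRotate,
                 seed = as.integer(seed), retryBudget = as.integer(retryBudget)),
            class = "AnatomyParams")
}

#' Hounsfield-unit model of the four tissue regimes
#'
#' @param background HU outside the body (air).
#' @param softTissue HU of soft tissue inside the body silhouette.
#' @param cancellous HU of the spongy bone interior.
#' @param cortical HU of the dense bone shell.
#' @param noiseAmplitude half-range of the additive i.i.d. uniform noise, HU.
#' @return An object of class \code{HUModel}; values must satisfy
#'   background < softTissue < cancellous < cortical.
#' @export
huModel <- function(background = -1000, softTissue = 40, cancellous = 300,
                    cortical = 1200, noiseAmplitude = 50) {
  if (!(background < softTissue && softTissue < cancellous &&
        cancellous < cortical))
    stop("HU values must be ordered background < softTissue < cancellous < cortical")
  if (!is.finite(noiseAmplitude) || noiseAmplitude < 0)
    stop("'noiseAmplitude' must be non-negative")
  structure(list(background = background, softTissue = softTissue,
                 cancellous = cancellous, cortical = cortical,
                 noiseAmplitude = noiseAmplitude), class = "HUModel")
}

.rot_zy <- function(az, ay) {
  cz <- cos(az); sz <- sin(az); cy <- cos(ay); sy <- sin(ay)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz %*% ry
}

# voxel coordinates (1-based, n x 3) within distance r of segment p0-p1
.raster_capsule <- function(p0, p1, r, dm) {
  lo <- pmax(floor(pmin(p0, p1) - r), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + r), dm)
  if (any(lo > hi)) return(matrix(0L, 0, 3))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  v <- p1 - p0; vv <- sum(v^2)
  w <- sweep(g, 2, p0)
  t <- if (vv > 0) pmin(pmax((w %*% v) / vv, 0), 1) else rep(0, nrow(g))
  dd <- (w[, 1] - t * v[1])^2 + (w[, 2] - t * v[2])^2 + (w[, 3] - t * v[3])^2
  g[dd <= r^2, , drop = FALSE]
}

.raster_sphere <- function(center, r, dm)
  .raster_capsule(center, center, r, dm)

.raster_disc <- function(center, r, h, dm) {
  lo <- pmax(floor(center - c(r, r, h)), 1)
  hi <- pmin(ceiling(center + c(r, r, h)), dm)
  if (any(lo > hi)) return(matrix(0L, 0, 3))
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  keep <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 <= r^2 &
    abs(g[, 3] - center[3]) <= h
  g[keep, , drop = FALSE]
}

.raster_box <- function(center, half, dm) {
  lo <- pmax(ceiling(center - half), 1)
  hi <- pmin(floor(center + half), dm)
  if (any(lo > hi)) return(matrix(0L, 0, 3))
  as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
}

.raster_polytube <- function(pts, r, dm) {
  segs <- lapply(seq_len(nrow(pts) - 1), function(i)
    .raster_capsule(pts[i, ], pts[i + 1, ], r, dm))
  unique(do.call(rbind, segs))
}

# guaranteed voxels along the bone's skeleton line (used at coarse scales
# where the nominal radius falls below one voxel)
.spine_coords <- function(pts, dm) {
  n <- nrow(pts)
  dens <- list()
  for (i in seq_len(n - 1)) {
    len <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
    m <- max(2L, ceiling(len * 2))
    t <- seq(0, 1, length.out = m)
    dens[[i]] <- cbind(pts[i, 1] + t * (pts[i + 1, 1] - pts[i, 1]),
                       pts[i, 2] + t * (pts[i + 1, 2] - pts[i, 2]),
                       pts[i, 3] + t * (pts[i + 1, 3] - pts[i, 3]))
  }
  p <- round(do.call(rbind, if (length(dens)) dens else list(pts)))
  p <- p[p[, 1] >= 1 & p[, 2] >= 1 & p[, 3] >= 1 &
           p[, 1] <= dm[1] & p[, 2] <= dm[2] & p[, 3] <= dm[3], , drop = FALSE]
  unique(p)
}

.bone_points <- function(bone, fscale, rscale, jitter) {
  # reference control points of the bone, jittered, then scaled to the grid
  pts <- switch(bone$family,
    sphere = matrix(bone$center, 1, 3, byrow = TRUE),
    disc = matrix(bone$center, 1, 3, byrow = TRUE),
    box = matrix(bone$center, 1, 3, byrow = TRUE),
    rod = rbind(bone$p0, bone$p1),
    tube = bone$pts)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  pts <- pts * jitter$scale
  if (bone$family %in% c("rod", "tube"))
    pts <- pts %*% t(.rot_zy(jitter$az, jitter$ay))
  pts <- sweep(pts, 2, ctr + jitter$t, `+`)
  sweep(pts, 2, fscale, `*`)
}

.raster_bone <- function(bone, dm, fscale, rscale, jitter) {
  pts <- .bone_points(bone, fscale, rscale, jitter)
  s <- jitter$scale * rscale
  coords <- switch(bone$family,
    sphere = .raster_sphere(pts[1, ], bone$r * s, dm),
    disc = .raster_disc(pts[1, ], bone$r * s, max(bone$h * s, 0.5), dm),
    box = .raster_box(pts[1, ], pmax(bone$half * fscale * jitter$scale, 0.5), dm),
    rod = .raster_capsule(pts[1, ], pts[2, ], bone$r * s, dm),
    tube = .raster_polytube(pts, bone$r * s, dm))
  unique(rbind(coords, .spine_coords(pts, dm)))
}

.bone_extent <- function(bone, fscale, rscale, jitter) {
  pts <- .bone_points(bone, fscale, rscale, jitter)
  s <- jitter$scale * rscale
  r <- switch(bone$family, sphere = bone$r * s, disc = bone$r * s,
              box = max(bone$half * fscale * jitter$scale), rod = bone$r * s,
              tube = bone$r * s)
  list(lo = apply(pts, 2, min) - r, hi = apply(pts, 2, max) + r)
}

#' Generate a randomised stick-figure skeleton
#'
#' Rasterises the 41-bone inventory of \code{params} into a label volume of
#' shape \code{params$volumeShape}.  Bones are drawn in label order into
#' still-free voxels; every bone is additionally guaranteed at least its
#' skeleton-line voxels so that all 41 labels are present at any grid
#' resolution.  The result is deterministic given \code{params$seed}.
#'
#' @param params an \code{\link{anatomyParams}} object.
#' @return A \linkS4class{LabelVolume} with \code{nClasses = 42}.
#' @export
generateSkeleton <- function(params = anatomyParams()) {
  stopifnot(inherits(params, "AnatomyParams"))
  dm <- params$volumeShape
  fscale <- dm / c(128, 128, 256)
  rscale <- mean(fscale)
  .run_with_seed(params$seed, {
    arr <- array(0L, dm)
    for (bone in params$boneInventory) {
      placed <- FALSE
      for (try in seq_len(params$retryBudget)) {
        jitter <- list(
          t = stats::runif(3, -params$jitterTranslate, params$jitterTranslate),
          scale = 1 + stats::runif(1, -params$jitterScale, params$jitterScale),
          az = stats::runif(1, -params$jitterRotate, params$jitterRotate) * pi / 180,
          ay = stats::runif(1, -params$jitterRotate, params$jitterRotate) * pi / 180)
        ext <- .bone_extent(bone, fscale, rscale, jitter)
        if (all(ext$lo >= 0.5) && all(ext$hi <= dm + 0.5)) { placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("bone %d: jitter keeps pushing the bone outside the volume (retry budget %d exhausted)",
                     bone$label, params$retryBudget))
      coords <- .raster_bone(bone, dm, fscale, rscale, jitter)
      free <- arr[coords] == 0L
      if (!any(free))
        stop(sprintf("bone %d could not be placed: all candidate voxels occupied",
                     bone$label))
      arr[coords[free, , drop = FALSE]] <- bone$label
    }
    present <- sort(unique(as.vector(arr)))
    missing <- setdiff(1:41, present)
    if (length(missing))
      stop("bones missing from the rasterised skeleton: ",
           paste(missing, collapse = ", "))
    LabelVolume(arr, nClasses = 42L)
  })
}

.default_compartments <- function() {
  list(head = 1L, torso = c(2:31, 36L, 41L), arm_left = c(32L, 33L),
       arm_right = c(34L, 35L), leg_left = c(37L, 38L),
       leg_right = c(39L, 40L))
}

#' Soft-tissue silhouette from per-compartment convex hulls
#'
#' Computes the convex hull of the bone voxels of each body compartment
#' (head, torso, each arm, each leg) and returns their union as the
#' soft-tissue body mask.  Per-compartment hulls avoid filling the space
#' between the limbs, which a single global hull would.
#'
#' @param labels a \linkS4class{LabelVolume} containing the skeleton.
#' @param compartments named list mapping compartment names to label
#'   vectors; defaults to the 41-bone inventory's grouping.
#' @return A \linkS4class{BinaryMask}; every bone voxel lies inside it.
#' @export
generateTissueHull <- function(labels, compartments = .default_compartments()) {
  stopifnot(is(labels, "LabelVolume"))
  arr <- labels@labels
  dm <- dim(arr)
  out <- array(FALSE, dm)
  for (nm in names(compartments)) {
    sel <- arr %in% compartments[[nm]]
    if (!any(sel))
      stop("compartment '", nm, "' contains no bone voxels")
    coords <- which(array(sel, dm), arr.ind = TRUE)
    out <- out | .convex_mask(coords, dm)
  }
  m <- out + 0L
  dim(m) <- dm
  new("BinaryMask", mask = m, spacing = labels@spacing, affine = labels@affine)
}

#' Render a CT volume from a skeleton and its soft-tissue hull
#'
#' Voxels get \code{background} HU outside the hull, \code{softTissue}
#' inside the hull but outside bone, \code{cortical} on the bone shell (bone
#' voxels with at least one face neighbour outside their own bone) and
#' \code{cancellous} in the bone interior, plus i.i.d. uniform noise in
#' \code{[-noiseAmplitude, +noiseAmplitude]}.  Noise values are quantised to
#' 1/256 HU so rendered volumes survive 32-bit NIfTI storage exactly.
#'
#' @param labels skeleton \linkS4class{LabelVolume}.
#' @param hull soft-tissue \linkS4class{BinaryMask} of the same shape.
#' @param hu a \code{\link{huModel}}.
#' @param seed integer seed for the noise field.
#' @return A \linkS4class{CTVolume}.
#' @export
renderCT <- function(labels, hull, hu = huModel(), seed = 1L) {
  stopifnot(is(labels, "LabelVolume"), is(hull, "BinaryMask"),
            inherits(hu, "HUModel"))
  arr <- labels@labels
  dm <- dim(arr)
  stopifnot(all(dm == dim(hull@mask)))
  shell <- .bone_shell(arr)
  ct <- array(hu$background, dm)
  ct[hull@mask == 1L] <- hu$softTissue
  ct[arr > 0L] <- hu$cancellous
  ct[shell] <- hu$cortical
  if (hu$noiseAmplitude > 0) {
    noise <- .run_with_seed(seed,
      round(stats::runif(prod(dm), -hu$noiseAmplitude, hu$noiseAmplitude) * 256) / 256)
    ct <- ct + noise
  }
  dim(ct) <- dm
  CTVolume(ct, spacing = labels@spacing, affine = labels@affine)
}

# bone voxels with a face neighbour carrying a different label (or background)
.bone_shell <- function(arr) {
  dm <- dim(arr)
  pad <- array(-1L, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- arr
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  differs <- array(FALSE, dm)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[2:(dm[1] + 1) + s[1], 2:(dm[2] + 1) + s[2], 2:(dm[3] + 1) + s[3]]
    differs <- differs | (nb != core)
  }
  differs & core > 0L
}

.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + as.numeric(index) * 1046527) %% 2147483647)
}

#' Generate a dataset of synthetic CT/label volume pairs
#'
#' Writes \code{nVolumes} (CT, label) NIfTI pairs with per-volume seeds
#' derived from the master seed by a counter scheme, plus a manifest CSV
#' assigning each case to the train/val/test split.  The defaults emulate
#' the published synthetic benchmark: 50 scans split 17/7/26.
#'
#' @param outDir output directory (created if missing).
#' @param nVolumes number of volume pairs.
#' @param split named integer vector \code{c(train=, val=, test=)} summing
#'   to \code{nVolumes}.
#' @param seed master seed.
#' @param params \code{\link{anatomyParams}} template; its per-volume seed is
#'   replaced by the derived seed.
#' @param hu \code{\link{huModel}} for rendering.
#' @return Invisibly, the manifest as a data.frame with columns
#'   \code{case}, \code{ct}, \code{seg}, \code{split}.
#' @export
generateDataset <- function(outDir, nVolumes = 50L,
                            split = c(train = 17L, val = 7L, test = 26L),
                            seed = 1L, params = anatomyParams(),
                            hu = huModel()) {
  if (sum(split) != nVolumes)
    stop("split must sum to nVolumes (", sum(split), " != ", nVolumes, ")")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create directory: ", outDir)
  splits <- rep(names(split), times = split)
  rows <- vector("list", nVolumes)
  for (i in seq_len(nVolumes)) {
    si <- .derive_seed(seed, i)
    params$seed <- si
    lab <- generateSkeleton(params)
    hullm <- generateTissueHull(lab)
    ct <- renderCT(lab, hullm, hu, seed = .derive_seed(si, 1L))
    ctPath <- file.path(outDir, sprintf("case_%04d_ct.nii.gz", i))
    segPath <- file.path(outDir, sprintf("case_%04d_seg.nii.gz", i))
    writeVolume(ct, ctPath)
    writeVolume(lab, segPath)
    rows[[i]] <- data.frame(case = sprintf("case_%04d", i), ct = ctPath,
                            seg = segPath, split = splits[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
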