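#' Confusion-set configuration for label correction
#'
#' A confusion set L groups bone classes that a model frequently mistakes
#' for one another (e.g. the vertebrae, or the ribs of one side); label
#' correction operates within each set independently.  The component cap u
#' bounds how many connected components per class are considered, which
#' bounds the pairwise adjacency work per set by |L|^2 * u.
#'
#' @param sets list of integer vectors of class ids (>= 1); sets must be
#'   pairwise disjoint.
#' @param cap maximum components considered per class (u).
#' @return A validated list of class \code{ConfusionSetConfig}.
#' @export
confusionSetConfig <- function(sets, cap = 100L) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a non-empty list of label vectors")
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  all <- unlist(sets)
  if (any(all < 1L)) stop("confusion sets may only contain labels >= 1")
  if (anyDuplicated(all)) stop("confusion sets must be pairwise disjoint")
  cap <- as.integer(cap)
  if (cap < 1L) stop("'cap' must be at least 1")
  structure(list(sets = sets, cap = cap), class = "ConfusionSetConfig")
}

#' Default confusion sets
#'
#' For the 42-class synthetic skeleton: five anatomical groups (vertebral
#' column, left ribs, right ribs, left limb + girdle, right limb + girdle).
#' For other class counts a contiguous partition of the foreground labels
#' into sets of 4-12 classes is returned as an editable starting point, the
#' sets ideally being refined from the confusion report of a validation
#' run.
#'
#' @param nClasses total class count N including background.
#' @param cap component cap u.
#' @return A \code{\link{confusionSetConfig}}.
#' @export
defaultConfusionSets <- function(nClasses = 42L, cap = 100L) {
  nClasses <- as.integer(nClasses)
  if (nClasses == 42L) {
    sets <- list(2:13,                       # vertebral column
                 seq(14L, 28L, 2L),          # left ribs
                 seq(15L, 29L, 2L),          # right ribs
                 c(30L, 32L, 33L, 37L, 38L), # left girdle + limb bones
                 c(31L, 34L, 35L, 39L, 40L)) # right girdle + limb bones
    return(confusionSetConfig(sets, cap))
  }
  n <- nClasses - 1L
  nSets <- max(1L, min(16L, n %/% 7L))
  sizes <- rep(n %/% nSets, nSets)
  extra <- n - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  sets <- lapply(seq_len(nSets), function(i)
    (c(0L, ends)[i] + 1L):ends[i])
  confusionSetConfig(sets, cap)
}

#' Connected components of the classes of one confusion set
#'
#' Components are found under the given connectivity, sorted per class by
#' decreasing size (ties: smaller first-voxel index first) and truncated to
#' the \code{cap} largest; the largest component of each class present is
#' flagged as that class's anchor.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param L integer vector of class ids to analyse.
#' @param cap component cap u.
#' @param connectivity 6 or 26 (voxel face or face+edge+corner adjacency).
#' @return list with \code{table}, a data.frame (class, component id, size,
#'   firstVoxel, anchor, withinCap), and \code{components}, the component-id
#'   volume (integer array, 0 = background/other classes).
#' @export
findComponents <- function(labels, L, cap = 100L, connectivity = 26L) {
  stopifnot(is(labels, "LabelVolume"))
  connectivity <- match.arg(as.character(connectivity), c("6", "26"))
  arr <- labels@labels
  sel <- arr
  sel[!(sel %in% as.integer(L))] <- 0L
  cc <- .cpp_cclabel(sel, dim(arr), as.integer(connectivity))
  tab <- data.frame(class = cc$class, component = seq_along(cc$class),
                    size = cc$size, firstVoxel = cc$first)
  tab <- tab[order(tab$class, -tab$size, tab$firstVoxel), , drop = FALSE]
  if (nrow(tab)) {
    rank <- stats::ave(seq_len(nrow(tab)), tab$class, FUN = seq_along)
    tab$anchor <- rank == 1L
    tab$withinCap <- rank <= cap
  } else {
    tab$anchor <- logical(0)
    tab$withinCap <- logical(0)
  }
  rownames(tab) <- NULL
  list(table = tab, components = cc$comp)
}

#' Connected-component label correction
#'
#' Within each confusion set L, the largest connected component of every
#' class is its anchor; every other (non-anchor) component of a class in L
#' that touches an anchor of a different class in L is relabelled to that
#' anchor's class.  Fragments touching several anchors go to the anchor with
#' the most touching voxel pairs (ties: lowest class id).  Fragments
#' adjacent to no anchor, anchors themselves, classes outside every set, and
#' the background are left unchanged, so the foreground voxel set is
#' conserved.  Reassignments are computed from the input labelling and
#' applied atomically per set, in a single pass.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param cfg a \code{\link{confusionSetConfig}}.
#' @param connectivity 6 or 26, used both for components and for adjacency.
#' @return A corrected \linkS4class{LabelVolume}; attribute
#'   \code{"diagnostics"} carries the number of fragment-anchor adjacency
#'   tests performed per set (each bounded by |L|^2 * u).
#' @export
correctLabels <- function(labels, cfg, connectivity = 26L) {
  stopifnot(is(labels, "LabelVolume"), inherits(cfg, "ConfusionSetConfig"))
  arr <- labels@labels
  out <- arr
  tests <- integer(length(cfg$sets))
  for (si in seq_along(cfg$sets)) {
    L <- cfg$sets[[si]]
    fc <- findComponents(labels, L, cap = cfg$cap,
                         connectivity = connectivity)
    tab <- fc$table
    if (nrow(tab) == 0L) next
    adj <- .cpp_adjacency_pairs(fc$components, dim(arr),
                                as.integer(connectivity))
    pairKey <- paste(adj$a, adj$b)
    anchors <- tab[tab$anchor, , drop = FALSE]
    frags <- tab[!tab$anchor & tab$withinCap, , drop = FALSE]
    nTests <- 0L
    moveComp <- integer(0)
    moveClass <- integer(0)
    for (fi in seq_len(nrow(frags))) {
      fcomp <- frags$component[fi]
      bestClass <- NA_integer_
      bestPairs <- 0
      for (ai in seq_len(nrow(anchors))) {
        if (anchors$class[ai] == frags$class[fi]) next
        nTests <- nTests + 1L
        acomp <- anchors$component[ai]
        key <- paste(min(fcomp, acomp), max(fcomp, acomp))
        hit <- match(key, pairKey)
        np <- if (is.na(hit)) 0 else adj$pairs[hit]
        if (np > bestPairs ||
            (np > 0 && np == bestPairs && anchors$class[ai] < bestClass)) {
          bestPairs <- np
          bestClass <- anchors$class[ai]
        }
      }
      if (bestPairs > 0) {
        moveComp <- c(moveComp, fcomp)
        moveClass <- c(moveClass, bestClass)
      }
    }
    if (length(moveComp)) {
      m <- match(fc$components, moveComp)
      sel <- !is.na(m)
      out[sel] <- moveClass[m[sel]]
    }
    tests[si] <- nTests
  }
  res <- new("LabelVolume", labels = out, nClasses = labels@nClasses,
             spacing = labels@spacing, affine = labels@affine)
  attr(res, "diagnostics") <- list(adjacencyTests = tests)
  res
}
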