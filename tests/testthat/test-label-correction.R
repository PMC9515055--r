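test_that("confusion-set configs are validated", {
  expect_error(confusionSetConfig(list(1:4, 4:8)), "disjoint")
  expect_error(confusionSetConfig(list(0:3)), ">= 1")
  expect_error(confusionSetConfig(list(1:4), cap = 0L), "at least 1")
  cfg <- defaultConfusionSets(42L)
  sizes <- lengths(cfg$sets)
  expect_true(all(sizes >= 4 & sizes <= 12))
  expect_false(anyDuplicated(unlist(cfg$sets)) > 0)
  cfg126 <- defaultConfusionSets(126L)
  expect_equal(length(cfg126$sets), 16L)
  expect_true(all(lengths(cfg126$sets) >= 4 & lengths(cfg126$sets) <= 12))
  expect_identical(sort(unlist(cfg126$sets)), 1:125)
})

test_that("findComponents anchors the largest component per class", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:4, 2:4, 2:4] <- 3L
  fc <- findComponents(LabelVolume(arr, nClasses = 6L), L = 3L)
  expect_equal(nrow(fc$table), 1L)
  expect_true(fc$table$anchor)
  # two blobs of size 10 and 4: the 10-blob is the anchor
  arr2 <- array(0L, c(10, 10, 10))
  arr2[1:10, 1, 1] <- 2L
  arr2[1:4, 5, 5] <- 2L
  fc2 <- findComponents(LabelVolume(arr2, nClasses = 6L), L = 2L)
  expect_equal(fc2$table$size, c(10L, 4L))
  expect_equal(fc2$table$anchor, c(TRUE, FALSE))
})

test_that("component labelling matches a BFS flood-fill oracle", {
  for (conn in c(6L, 26L)) for (seed in 1:3) {
    set.seed(seed)
    arr <- array(sample(0:3, 9^3, TRUE, prob = c(0.82, 0.06, 0.06, 0.06)),
                 c(9, 9, 9))
    cc <- BoneBEM:::.cpp_cclabel(arr, dim(arr), conn)
    oracle <- bfs_components(arr, conn)
    # identical partitions up to component renumbering
    expect_equal(max(oracle), length(cc$size))
    key_mine <- as.vector(cc$comp)[arr != 0L]
    key_oracle <- as.vector(oracle)[arr != 0L]
    expect_true(all(tapply(key_oracle, key_mine,
                           function(v) length(unique(v))) == 1L))
    expect_true(all(tapply(key_mine, key_oracle,
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("fragments adjacent to an anchor of another class are absorbed", {
  # the fragmented-rib scenario: an anchor of class 2, a 3-voxel stray
  # fragment of class 5 touching it, and class 5's own anchor elsewhere
  arr <- array(0L, c(10, 10, 10))
  arr[2:6, 2:3, 2:3] <- 2L       # class 2 anchor
  arr[7:9, 2, 2] <- 5L           # fragment of class 5, touches class 2
  arr[2:8, 8:9, 8:9] <- 5L       # class 5 anchor, far away
  lab <- LabelVolume(arr, nClasses = 8L)
  cfg <- confusionSetConfig(list(c(2L, 3L, 5L, 7L)))
  out <- correctLabels(lab, cfg)
  expect_true(all(labelArray(out)[7:9, 2, 2] == 2L))
  # anchors unchanged
  expect_true(all(labelArray(out)[2:6, 2:3, 2:3] == 2L))
  expect_true(all(labelArray(out)[2:8, 8:9, 8:9] == 5L))
  # foreground voxel set conserved
  expect_identical(labelArray(out) != 0L, arr != 0L)
  # label set can only shrink
  expect_true(all(unique(as.vector(labelArray(out))) %in%
                    unique(as.vector(arr))))
})

test_that("isolated fragments are kept, not deleted", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:6, 2:3, 2:3] <- 2L
  arr[9, 9, 9] <- 5L             # fragment adjacent to nothing
  arr[2:8, 6, 6] <- 5L           # class 5 anchor
  lab <- LabelVolume(arr, nClasses = 8L)
  out <- correctLabels(lab, confusionSetConfig(list(c(2L, 3L, 5L, 7L))))
  expect_equal(labelArray(out)[9, 9, 9], 5L)
  expect_identical(labelArray(out), arr)
})

test_that("classes outside every set and whole untouched sets stay bitwise equal", {
  set.seed(6)
  arr <- array(sample(0:6, 12^3, TRUE, prob = c(0.8, rep(0.2 / 6, 6))),
               c(12, 12, 12))
  lab <- LabelVolume(arr, nClasses = 8L)
  out <- correctLabels(lab, confusionSetConfig(list(c(1L, 2L, 3L, 4L))))
  untouched <- !(arr %in% 1:4)
  expect_identical(labelArray(out)[untouched], arr[untouched])
  expect_identical(labelArray(out) != 0L, arr != 0L)
  # one component per class: nothing moves
  solid <- array(0L, c(8, 8, 8))
  solid[1:3, 1:3, 1] <- 1L
  solid[5:7, 5:7, 5] <- 2L
  out2 <- correctLabels(LabelVolume(solid, nClasses = 5L),
                        confusionSetConfig(list(1:4)))
  expect_identical(labelArray(out2), solid)
})

test_that("multi-anchor fragments go to the strongest contact, ties to the lowest class", {
  base <- array(0L, c(12, 12, 12))
  base[1:4, 1:4, 1:4] <- 4L                   # anchor class 4, left of the gap
  base[5, 2, 2] <- 6L                         # one-voxel fragment in the gap
  base[1:6, 10, 10] <- 6L                     # class 6 anchor, far away
  # tie: class 2 anchor mirrors class 4 across the gap (9 pairs each)
  tie <- base
  tie[6:9, 1:4, 1:4] <- 2L
  out <- correctLabels(LabelVolume(tie, nClasses = 8L),
                       confusionSetConfig(list(c(2L, 4L, 6L, 7L))))
  expect_equal(labelArray(out)[5, 2, 2], 2L)
  # asymmetric contact: a slimmer class 2 anchor offers fewer touching pairs
  uneven <- base
  uneven[6:9, 1:2, 1:4] <- 2L                 # 6 pairs versus 9 for class 4
  out2 <- correctLabels(LabelVolume(uneven, nClasses = 8L),
                        confusionSetConfig(list(c(2L, 4L, 6L, 7L))))
  expect_equal(labelArray(out2)[5, 2, 2], 4L)
})

test_that("adjacency testing respects the |L|^2 * u bound on fragmented input", {
  set.seed(8)
  arr <- array(0L, c(20, 20, 20))
  # heavily fragmented sprinkle of four classes
  idx <- sample(20^3, 900)
  arr[idx] <- sample(2:5, 900, TRUE)
  lab <- LabelVolume(arr, nClasses = 6L)
  cfg <- confusionSetConfig(list(2:5), cap = 100L)
  out <- correctLabels(lab, cfg)
  diag <- attr(out, "diagnostics")
  expect_lte(diag$adjacencyTests[1], 4^2 * 100)
  expect_identical(labelArray(out) != 0L, arr != 0L)
})

test_that("connectivity choice changes diagonal adjacency as documented", {
  arr <- array(0L, c(6, 6, 6))
  arr[1:3, 1:3, 1:3] <- 2L
  arr[4, 4, 4] <- 5L            # touches class 2 only diagonally
  arr[6, 6, 6] <- 0L
  arr[1:4, 6, 6] <- 5L          # anchor of class 5
  lab <- LabelVolume(arr, nClasses = 6L)
  cfg <- confusionSetConfig(list(c(2L, 3L, 4L, 5L)))
  out26 <- correctLabels(lab, cfg, connectivity = 26L)
  expect_equal(labelArray(out26)[4, 4, 4], 2L)
  out6 <- correctLabels(lab, cfg, connectivity = 6L)
  expect_equal(labelArray(out6)[4, 4, 4], 5L)
})
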