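lab_from <- function(v, N = NULL) LabelVolume(array(as.integer(v),
                                                    c(length(v), 1, 1)),
                                              nClasses = N)

test_that("per-class Dice follows the set-overlap formula", {
  set.seed(1)
  arr <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
  gt <- LabelVolume(arr, nClasses = 4L)
  ident <- dscPerClass(gt, gt)
  expect_true(all(ident$dsc[ident$presentInGt] == 1))
  # disjoint supports
  a <- lab_from(c(1, 1, 0, 0), 3L)
  b <- lab_from(c(0, 0, 1, 1), 3L)
  expect_equal(dscPerClass(a, b)$dsc[1], 0)
  # |X| = 3, |Y| = 4, overlap 2 -> 4/7
  pred <- lab_from(c(1, 1, 1, 0, 0, 0, 0), 2L)
  gt2 <- lab_from(c(1, 1, 0, 1, 1, 0, 0), 2L)
  expect_equal(dscPerClass(pred, gt2)$dsc[1], 4 / 7)
  # symmetry
  for (seed in 1:4) {
    set.seed(seed)
    x <- lab_from(sample(0:2, 30, TRUE), 3L)
    y <- lab_from(sample(0:2, 30, TRUE), 3L)
    expect_equal(dscPerClass(x, y)$dsc, dscPerClass(y, x)$dsc)
  }
  expect_error(dscPerClass(a, LabelVolume(array(0L, c(2, 2, 2)))),
               "disagree")
})

test_that("summaries use the detected classes only and report the detected fraction", {
  s <- data.frame(class = 1:3, dsc = c(1, 0.8, 0.6),
                  hasTruePositive = TRUE, presentInGt = TRUE,
                  predVoxels = 1, gtVoxels = 1)
  sm <- summarizeScores(s)
  expect_equal(sm$median, 0.8)
  expect_equal(sm$detectedFraction, 1)
  s2 <- data.frame(class = 1:3, dsc = c(0.9, 0.9, 0),
                   hasTruePositive = c(TRUE, TRUE, FALSE),
                   presentInGt = TRUE, predVoxels = c(1, 1, 0),
                   gtVoxels = 1)
  sm2 <- summarizeScores(s2)
  expect_equal(sm2$median, 0.9)
  expect_equal(sm2$detectedFraction, 2 / 3)
  expect_match(formatSummary(sm2), "^0\\.90_\\{-0\\.00\\}\\^\\{\\+0\\.00\\}, \\(0\\.67\\)$")
  s3 <- s2
  s3$dsc <- 0
  s3$hasTruePositive <- FALSE
  expect_error(summarizeScores(s3), "no class has a true-positive")
  # percentile order invariant
  expect_lte(sm$p16, sm$median)
  expect_lte(sm$median, sm$p84)
})

test_that("confusion matrices match the four-voxel hand count", {
  gt <- lab_from(c(0, 0, 1, 1), 2L)
  pred <- lab_from(c(0, 1, 1, 0), 2L)
  raw <- confusionMatrixVolumes(pred, gt)
  expect_equal(unname(raw), rbind(c(1, 1), c(1, 1)))
  nrm <- confusionMatrixVolumes(pred, gt, normalize = TRUE)
  expect_equal(unname(nrm), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  # trace counts correct voxels, total counts all voxels
  set.seed(2)
  a <- lab_from(sample(0:3, 50, TRUE), 4L)
  b <- lab_from(sample(0:3, 50, TRUE), 4L)
  cm <- confusionMatrixVolumes(b, a)
  expect_equal(sum(diag(cm)), sum(labelArray(a) == labelArray(b)))
  expect_equal(sum(cm), 50)
  nm <- confusionMatrixVolumes(b, a, normalize = TRUE)
  rs <- rowSums(nm)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  # identity on perfect prediction
  ni <- confusionMatrixVolumes(a, a, normalize = TRUE)
  present <- sort(unique(as.vector(labelArray(a)))) + 1L
  expect_equal(unname(ni[present, present]), diag(length(present)))
})

test_that("confusion reports rank off-diagonal rates like a full sort", {
  expect_equal(nrow(confusionReport(diag(4))), 0L)
  m <- diag(3) * 0.7
  m[1, 2] <- 0.3
  expect_equal(confusionReport(m)[1, ], data.frame(gtClass = 0L,
                                                   predClass = 1L,
                                                   rate = 0.3))
  set.seed(5)
  r <- matrix(runif(36), 6)
  rep <- confusionReport(r, topK = 36L)
  off <- r[row(r) != col(r)]
  expect_equal(rep$rate, sort(off, decreasing = TRUE))
})

test_that("BEM with the ground-truth mask eliminates bone-to-background errors", {
  for (seed in 1:3) {
    set.seed(seed)
    gtArr <- array(sample(0:4, 10^3, TRUE), c(10, 10, 10))
    gt <- LabelVolume(gtArr, nClasses = 5L)
    P <- random_prob_volume(seed + 10, c(10L, 10L, 10L), N = 5L)
    bem <- bemCombine(P, binarizeLabels(gt))
    nm <- confusionMatrixVolumes(bem, gt, normalize = TRUE)
    expect_true(all(nm[2:5, 1] == 0))
  }
})
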