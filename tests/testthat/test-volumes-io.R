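test_that("NIfTI write/read round-trips all three volume kinds exactly", {
  dir <- withr::local_tempdir()
  set.seed(42)
  ct <- CTVolume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(1, 1.5, 2))
  f <- file.path(dir, "ct.nii.gz")
  writeVolume(ct, f)
  r <- readVolume(f, "ct")
  expect_identical(voxels(r), voxels(ct))
  expect_equal(spacing(r), spacing(ct))

  lab <- LabelVolume(array(sample(0:9, 120, TRUE), c(6, 5, 4)),
                     nClasses = 10L, spacing = c(2, 2, 2))
  f2 <- file.path(dir, "seg.nii.gz")
  writeVolume(lab, f2)
  r2 <- readVolume(f2, "labels", nClasses = 10L)
  expect_identical(labelArray(r2), labelArray(lab))

  msk <- binarizeLabels(lab)
  f3 <- file.path(dir, "mask.nii.gz")
  writeVolume(msk, f3)
  expect_identical(maskArray(readVolume(f3, "mask")), maskArray(msk))
})

test_that("read validates existence, dimensionality, ranges and integrality", {
  dir <- withr::local_tempdir()
  expect_error(readVolume(file.path(dir, "absent.nii.gz"), "ct"),
               "not found")
  # labels beyond the declared class count
  lab <- LabelVolume(array(c(rep(0L, 23), 200L), c(2, 3, 4)))
  f <- file.path(dir, "big.nii.gz")
  writeVolume(lab, f)
  expect_error(readVolume(f, "labels", nClasses = 126L), "outside")
  # a mask stored as floating point 0.0/1.0 is fine
  img <- RNifti::asNifti(array(c(0, 1, 1, 0, 0, 0, 1, 0), c(2, 2, 2)))
  f2 <- file.path(dir, "fmask.nii.gz")
  RNifti::writeNifti(img, f2, datatype = "double")
  m <- readVolume(f2, "mask")
  expect_s4_class(m, "BinaryMask")
  expect_equal(sum(maskArray(m)), 3L)
  # far-from-integer values are rejected for labels
  img3 <- RNifti::asNifti(array(c(0, 0.4, 1, 0, 0, 0, 1, 0), c(2, 2, 2)))
  f3 <- file.path(dir, "frac.nii.gz")
  RNifti::writeNifti(img3, f3, datatype = "double")
  expect_error(readVolume(f3, "labels"), "not integral")
  expect_error(writeVolume(lab, file.path(dir, "no/such/dir/x.nii.gz")),
               "directory")
})

test_that("resampling honours interpolation rules and the shape formula", {
  set.seed(7)
  ct <- CTVolume(array(rnorm(16 * 12 * 8), c(16, 12, 8)), spacing = c(1, 1, 1))
  # identity resample
  same <- resampleVolume(ct, c(1, 1, 1))
  expect_identical(voxels(same), voxels(ct))
  # constant CT downsampled 2x: constant volume with halved shape
  const <- CTVolume(array(5, c(16, 12, 8)))
  half <- resampleVolume(const, c(2, 2, 2))
  expect_equal(dim(half), c(8, 6, 4))
  expect_true(all(voxels(half) == 5))
  # label sets shrink (or stay) under nearest-neighbour resampling
  for (seed in 1:5) {
    set.seed(seed)
    lab <- LabelVolume(array(sample(0:6, 15 * 10 * 9, TRUE), c(15, 10, 9)),
                       nClasses = 7L)
    rs <- resampleVolume(lab, c(1.7, 2.3, 1.1))
    expect_true(all(unique(as.vector(labelArray(rs))) %in%
                      unique(as.vector(labelArray(lab)))))
    expect_equal(dim(rs), as.integer(floor(c(15, 10, 9) / c(1.7, 2.3, 1.1) + 0.5)))
  }
  # idempotence at the target spacing
  rs1 <- resampleVolume(ct, c(2, 1.5, 1))
  rs2 <- resampleVolume(rs1, c(2, 1.5, 1))
  expect_identical(voxels(rs1), voxels(rs2))
  expect_error(resampleVolume(ct, c(0, 1, 1)), "positive")
})

test_that("binarizeLabels marks exactly the nonzero voxels", {
  allbg <- LabelVolume(array(0L, c(4, 4, 4)), nClasses = 5L)
  expect_true(all(maskArray(binarizeLabels(allbg)) == 0L))
  set.seed(3)
  arr <- array(sample(c(0L, 5L, 17L), 4^3, TRUE), c(4, 4, 4))
  lab <- LabelVolume(arr, nClasses = 18L)
  m <- binarizeLabels(lab)
  expect_true(all(maskArray(m)[arr %in% c(5L, 17L)] == 1L))
  expect_equal(sum(maskArray(m)), sum(arr != 0L))
})

test_that("volume classes enforce their invariants", {
  expect_error(CTVolume(array(c(1, NA, 1, 1), c(2, 2, 1))), "finite")
  expect_error(LabelVolume(array(3L, c(2, 2, 2)), nClasses = 3L),
               "label values")
  expect_error(BinaryMask(array(2L, c(2, 2, 2))), "0 or 1")
  expect_error(CTVolume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  p <- array(0.5, c(2, 2, 2, 2))
  expect_s4_class(ProbabilityVolume(p), "ProbabilityVolume")
  expect_error(ProbabilityVolume(array(0.4, c(2, 2, 2, 2))), "sum to 1")
})
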