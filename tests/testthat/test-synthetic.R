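test_that("default skeletons contain exactly bone labels 1..41 at 128x128x256", {
  lab <- generateSkeleton(anatomyParams(seed = 7L))
  expect_equal(dim(lab), c(128L, 128L, 256L))
  expect_identical(sort(setdiff(unique(as.vector(labelArray(lab))), 0L)),
                   1:41)
  expect_equal(nClasses(lab), 42L)
})

test_that("skeleton generation is deterministic in the seed", {
  p <- anatomyParams(volumeShape = c(32L, 32L, 64L), seed = 5L)
  a <- generateSkeleton(p)
  b <- generateSkeleton(p)
  expect_identical(labelArray(a), labelArray(b))
  p2 <- anatomyParams(volumeShape = c(32L, 32L, 64L), seed = 6L)
  c <- generateSkeleton(p2)
  expect_gt(sum(labelArray(a) != labelArray(c)), 0)
})

test_that("all 41 bones survive rasterisation at coarse grids", {
  for (seed in c(1L, 23L)) {
    lab <- generateSkeleton(anatomyParams(volumeShape = c(32L, 32L, 64L),
                                          seed = seed))
    expect_identical(sort(setdiff(unique(as.vector(labelArray(lab))), 0L)),
                     1:41)
  }
})

test_that("the tissue hull wraps every bone voxel", {
  lab <- generateSkeleton(anatomyParams(volumeShape = c(48L, 48L, 96L),
                                        seed = 2L))
  h <- generateTissueHull(lab)
  expect_true(all(maskArray(h)[labelArray(lab) > 0L] == 1L))
  expect_gte(sum(maskArray(h)), sum(labelArray(lab) > 0L))
  expect_error(generateTissueHull(lab, compartments = list(empty = 99L)),
               "no bone voxels")
})

test_that("rendering fills the four HU regimes plus bounded uniform noise", {
  lab <- generateSkeleton(anatomyParams(volumeShape = c(32L, 32L, 64L),
                                        seed = 3L))
  h <- generateTissueHull(lab)
  hu0 <- huModel(noiseAmplitude = 0)
  ct0 <- renderCT(lab, h, hu0, seed = 1L)
  vals <- sort(unique(as.vector(voxels(ct0))))
  expect_identical(vals, sort(c(hu0$background, hu0$softTissue,
                                hu0$cancellous, hu0$cortical)))
  # all-background labels with an empty hull give a constant volume
  bg <- LabelVolume(array(0L, c(8L, 8L, 8L)), nClasses = 42L)
  empty <- BinaryMask(array(0L, c(8L, 8L, 8L)))
  expect_true(all(voxels(renderCT(bg, empty, hu0, 1L)) == hu0$background))
  # noise stays within the amplitude around the noiseless render
  hu <- huModel(noiseAmplitude = 50)
  ct <- renderCT(lab, h, hu, seed = 9L)
  dev <- abs(voxels(ct) - voxels(ct0))
  expect_lte(max(dev), 50)
  # labels and CT stay aligned: bone voxels are at least cancellous - noise
  expect_true(all(voxels(ct)[labelArray(lab) > 0L] >=
                    hu$cancellous - hu$noiseAmplitude))
  expect_error(huModel(background = 100, softTissue = 40), "ordered")
})

test_that("dataset generation writes pairs, a manifest and is bit-reproducible", {
  m <- mini_dataset()
  expect_equal(nrow(m), 4L)
  expect_true(all(file.exists(m$ct)))
  expect_true(all(file.exists(m$seg)))
  expect_equal(as.vector(table(m$split)[c("test", "train")]), c(2L, 2L))
  expect_error(generateDataset(tempdir(), nVolumes = 3L,
                               split = c(train = 1L, val = 1L, test = 2L)),
               "sum")
  dir2 <- file.path(tempdir(), "bonebem-mini-rerun")
  m2 <- generateDataset(dir2, nVolumes = 4L,
                        split = c(train = 2L, val = 0L, test = 2L),
                        seed = 11L,
                        params = anatomyParams(volumeShape = c(32L, 32L, 64L)))
  expect_identical(unname(tools::md5sum(m$ct)), unname(tools::md5sum(m2$ct)))
  expect_identical(unname(tools::md5sum(m$seg)), unname(tools::md5sum(m2$seg)))
  unlink(dir2, recursive = TRUE)
})
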