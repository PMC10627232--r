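test_that("inner-percentile filter trims symmetric tails", {
  expect_identical(pool_and_filter(1:100), 6:95)
  expect_equal(pool_and_filter(5), 5)
  expect_equal(pool_and_filter(rep(3.2, 17)), rep(3.2, 17))
  expect_error(pool_and_filter(numeric(0)), "empty")
})

test_that("filter keeps about inner_fraction of random samples and stays in band", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:400, 1)
    x <- rnorm(n)
    kept <- pool_and_filter(x)
    expect_lte(abs(length(kept) - 0.9 * n), 1 + 0.9)
    lo <- quantile(x, 0.05, type = 7); hi <- quantile(x, 0.95, type = 7)
    expect_true(all(kept >= lo & kept <= hi))
    # survivor order preserved
    expect_identical(kept, x[x >= lo & x <= hi])
  }
})

test_that("filtering a metric sample is idempotent and tracks provenance", {
  s <- metric_sample("conspicuity", "A", "GTV", as.numeric(1:100),
                     data.frame(slice = 1:100))
  f1 <- pool_and_filter(s)
  expect_true(f1$filtered)
  expect_equal(f1$values, 6:95)
  expect_equal(f1$provenance$slice, 6:95)
  expect_identical(pool_and_filter(f1), f1)
})

test_that("volume and mask constructors enforce their invariants", {
  arr <- array(rnorm(60), c(5, 4, 3))
  v <- volume_image(arr, c(1, 1, 2), "S1", "P1")
  expect_equal(v$spacing_mm, c(1, 1, 2))
  arr[2, 2, 2] <- NaN
  expect_error(volume_image(arr, c(1, 1, 2)), "non-finite")
  expect_error(volume_image(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  m <- structure_mask(array(c(0, 255), c(2, 2, 2)), c(1, 1, 1), "GTV")
  expect_equal(sum(m$voxels), 4)        # binarised, count preserved
  expect_false(mask_is_empty(m))
  expect_true(mask_is_empty(structure_mask(array(0, c(2, 2, 2)),
                                           c(1, 1, 1), "GTV")))
})

test_that("NIfTI round trip preserves grids, spacing, and mask bits", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
  v <- volume_image(arr, c(1, 1, 1), "S1", "P1")
  p <- file.path(dir, "vol.nii.gz")
  write_nifti_object(v, p)
  v2 <- load_volume(p, "S1", "P1")
  expect_equal(v2$spacing_mm, c(1, 1, 1))
  expect_equal(v2$intensities, arr, tolerance = 1e-6)

  m <- ball_mask(c(10, 10, 5), c(1, 1, 2), c(5, 5, 3), 2.5)
  pm <- file.path(dir, "mask.nii.gz")
  write_nifti_object(m, pm)
  m2 <- load_mask(pm, "GTV")
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$spacing_mm, c(1, 1, 2))
  # second round trip is bit-identical
  pm2 <- file.path(dir, "mask2.nii.gz")
  write_nifti_object(m2, pm2)
  expect_identical(load_mask(pm2, "GTV")$voxels, m2$voxels)
})

test_that("degenerate NIfTI inputs are rejected or squeezed", {
  dir <- withr::local_tempdir()
  img4 <- RNifti::asNifti(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  p4 <- file.path(dir, "vol4d.nii")
  RNifti::writeNifti(img4, p4)
  expect_equal(dim(load_volume(p4)$intensities), c(8, 8, 4))

  bad <- array(rnorm(8 * 8 * 4), c(8, 8, 4)); bad[1] <- NA
  pbad <- file.path(dir, "nan.nii")
  RNifti::writeNifti(RNifti::asNifti(bad), pbad)
  expect_error(load_volume(pbad), "non-finite")

  v <- volume_image(array(0, c(6, 6, 3)), c(1, 1, 1))
  wrong <- structure_mask(array(1, c(5, 6, 3)), c(1, 1, 1), "GTV")
  expect_error(rubriq:::check_same_grid(wrong, v), "does not match")
})

test_that("sequence_structure_pair rejects mixed tags", {
  m1 <- ball_mask(c(8, 8, 8), c(1, 1, 1), c(4, 4, 4), 2, observer_id = "O1")
  m2 <- ball_mask(c(8, 8, 8), c(1, 1, 1), c(4, 4, 4), 2, observer_id = "O2")
  expect_s3_class(sequence_structure_pair(list(m1, m2)),
                  "sequence_structure_pair")
  m3 <- m2; m3$sequence_id <- "other"
  expect_error(sequence_structure_pair(list(m1, m3)), "share")
})
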