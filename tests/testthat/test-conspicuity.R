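# Cube mask at 1 mm spacing whose core / surround-ring regions are derived
# independently from the brute-force distance transform.
conspicuity_fixture <- function() {
  g <- c(15, 15, 9)
  vox <- array(FALSE, g); vox[6:10, 6:10, 4:6] <- TRUE
  mask <- structure_mask(vox, c(1, 1, 1), "GTV")
  d_out <- brute_edt(vox, c(1, 1, 1))
  d_in <- brute_edt(!vox, c(1, 1, 1))
  core <- vox & d_in > 1 + 1e-7
  ring <- (d_out <= 2 + 1e-7) & !(d_out <= 1 + 1e-7)
  list(grid = g, mask = mask, core = core, ring = ring)
}

test_that("slice conspicuity equals contrast over ring SD under the stated regions", {
  fx <- conspicuity_fixture()
  vol <- volume_image(array(50, fx$grid), c(1, 1, 1))
  # ring gets a deterministic +/-10 pattern around 50, core is 100
  ringvals <- rep(c(40, 60), length.out = sum(fx$ring))
  vol$intensities[fx$ring] <- ringvals
  vol$intensities[fx$core] <- 100
  fam <- mask_family(fx$mask, c(1, 2))
  s <- 5   # middle slice
  core_s <- fx$core[, , s]; ring_s <- fx$ring[, , s]
  img <- vol$intensities[, , s]
  expected <- abs(mean(img[core_s]) - mean(img[ring_s])) / sd(img[ring_s])
  expect_equal(slice_conspicuity(vol, fam, s), expected)
})

test_that("zero contrast gives zero and flat rings are capped, not infinite", {
  fx <- conspicuity_fixture()
  vol <- volume_image(array(50, fx$grid), c(1, 1, 1))
  vol$intensities[fx$ring] <- rep(c(45, 55), length.out = sum(fx$ring))
  vol$intensities[fx$core] <- mean(c(45, 55))
  fam <- mask_family(fx$mask, c(1, 2))
  expect_equal(slice_conspicuity(vol, fam, 5), 0)

  flat <- volume_image(array(50, fx$grid), c(1, 1, 1))
  flat$intensities[fx$core] <- 60
  v <- slice_conspicuity(flat, fam, 5, eps_floor = 1e-3)
  expect_true(isTRUE(attr(v, "capped")))
  expect_equal(as.numeric(v), 10 / 1e-3)
})

test_that("conspicuity is invariant to intensity shift and positive scaling", {
  set.seed(41)
  fx <- conspicuity_fixture()
  vol <- volume_image(array(rnorm(prod(fx$grid), 80, 12), fx$grid),
                      c(1, 1, 1))
  vol$intensities[fx$core] <- vol$intensities[fx$core] + 60
  fam <- mask_family(fx$mask, c(1, 2))
  base <- slice_conspicuity(vol, fam, 5)
  shifted <- vol; shifted$intensities <- vol$intensities + 500
  scaled <- vol; scaled$intensities <- vol$intensities * 4.2
  expect_equal(slice_conspicuity(shifted, fam, 5), base)
  expect_equal(slice_conspicuity(scaled, fam, 5), base)
})

test_that("per-slice series counts occupied slices and skips invalid ones", {
  m <- ball_mask(c(24, 24, 20), c(1, 1, 1), c(12, 12, 10), 6)
  vol <- volume_image(array(rnorm(24 * 24 * 20, 100, 10), c(24, 24, 20)),
                      c(1, 1, 1))
  vol$intensities[m$voxels] <- vol$intensities[m$voxels] + 50
  sl <- conspicuity_slices(vol, m)
  occupied <- which(apply(m$voxels, 3, any))
  expect_lte(nrow(sl), length(occupied))
  expect_true(all(sl$slice %in% occupied))
  # slices near the poles lose their 1 mm-contracted core and are skipped
  expect_lt(nrow(sl), length(occupied))
  expect_true(all(is.finite(sl$value)))
})

test_that("pooled conspicuity series filters to about 90% with provenance", {
  set.seed(42)
  g <- c(24, 24, 20)
  m <- ball_mask(g, c(1, 1, 1), c(12, 12, 10), 6, sequence_id = "S1")
  mk_vol <- function() {
    v <- volume_image(array(rnorm(prod(g), 100, 10), g), c(1, 1, 1), "S1")
    v$intensities[m$voxels] <- v$intensities[m$voxels] + 40
    v
  }
  volumes <- list(P1 = mk_vol(), P2 = mk_vol())
  masks <- list(P1 = list(O1 = m, O2 = m), P2 = list(O1 = m, O2 = m))
  out <- conspicuity_series(volumes, masks)
  n_raw <- 4 * nrow(conspicuity_slices(volumes$P1, m))
  expect_true(out$filtered)
  expect_lte(abs(length(out$values) - 0.9 * n_raw), 2)
  expect_equal(nrow(out$provenance), length(out$values))
  # identical volumes for two "sequences" give identical samples
  out2 <- conspicuity_series(volumes, masks)
  expect_identical(out$values, out2$values)
})
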