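test_that("phantom generation is seed-deterministic", {
  cfg <- tiny_phantom_config(seed = 5)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1$volumes$P01$NonFS$intensities,
                   s2$volumes$P01$NonFS$intensities)
  expect_identical(s1$observer_masks$P01$NonFS$GTV$O2$voxels,
                   s2$observer_masks$P01$NonFS$GTV$O2$voxels)
  s3 <- generate_phantom(tiny_phantom_config(seed = 6))
  expect_false(identical(s1$volumes$P01$NonFS$intensities,
                         s3$volumes$P01$NonFS$intensities))
})

test_that("phantom intensities recover configured noise and fat suppression", {
  cfg <- tiny_phantom_config(seed = 9, noise_sd = 10,
                             fat_suppression = c(NonFS = 1, SPAIR1 = 0.05))
  st <- generate_phantom(cfg)
  air <- st$truth_masks$P01$noise$voxels
  fat <- st$truth_masks$P01$fat$voxels
  n_air <- sum(air)
  sd_air <- sd(st$volumes$P01$NonFS$intensities[air])
  se_sd <- 10 / sqrt(2 * (n_air - 1))
  expect_lt(abs(sd_air - 10), 3 * se_sd)

  fat_ns <- mean(st$volumes$P01$NonFS$intensities[fat])
  fat_sp <- mean(st$volumes$P01$SPAIR1$intensities[fat])
  ratio <- fat_ns / fat_sp
  expect_lt(abs(ratio - 20) / 20, 0.1)    # 1 / 0.05
})

test_that("configs with invalid geometry or parameters are rejected", {
  expect_error(phantom_config(grid_dim = c(36, 36, 24)), "overlap")
  expect_error(phantom_config(grid_dim = c(10, 10, 6)), "empty|overlap")
  expect_error(tiny_phantom_config(noise_sd = 0), "positive")
  expect_error(tiny_phantom_config(background_mean = -5), "non-negative")
})

test_that("observer jitter behaves at its limits and in between", {
  truth <- ball_mask(c(24, 24, 20), c(1, 1, 1), c(12, 12, 10), 10,
                     subject_id = "P1", sequence_id = "S1")
  none <- simulate_observer_masks(truth, jitter_radius_mm = 0,
                                  translation_sd_mm = 0, n_observers = 4,
                                  seed = 1)
  expect_length(none, 4)
  for (m in none) expect_identical(m$voxels, truth$voxels)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dice(none[[i]], none[[j]]), 1)

  mean_pair_dsc <- function(radius, seed) {
    ms <- simulate_observer_masks(truth, jitter_radius_mm = radius,
                                  translation_sd_mm = 0, n_observers = 4,
                                  seed = seed)
    idx <- combn(4, 2)
    mean(vapply(seq_len(ncol(idx)), function(k)
      dice(ms[[idx[1, k]]], ms[[idx[2, k]]]), numeric(1)))
  }
  d2 <- vapply(1:6, function(s) mean_pair_dsc(2, s), numeric(1))
  d4 <- vapply(1:6, function(s) mean_pair_dsc(4, s), numeric(1))
  expect_true(all(d2 > 0.6 & d2 < 1))
  expect_lt(mean(d4), mean(d2))   # agreement decays with jitter
})

test_that("extreme jitter falls back to a clamped radius with a warning", {
  truth <- ball_mask(c(12, 12, 10), c(1, 1, 1), c(6, 6, 5), 2,
                     subject_id = "P1", sequence_id = "S1")
  w <- capture_warnings(
    ms <- simulate_observer_masks(truth, jitter_radius_mm = 6,
                                  translation_sd_mm = 0, n_observers = 8,
                                  seed = 3))
  expect_true(any(grepl("emptied", w)))
  for (m in ms) expect_false(mask_is_empty(m))
})

test_that("simulated qualitative tables honour favourability and seeds", {
  cfg <- tiny_phantom_config(seed = 5, n_subjects = 1, n_observers = 2)
  st <- generate_phantom(cfg)
  q_neutral <- simulate_qualitative_feedback(st, seed = 11)
  cs <- comment_samples(q_neutral)
  for (sq in names(cs)) for (g in names(cs[[sq]]))
    expect_true(all(cs[[sq]][[g]]$values == 0))

  fav <- list(NonFS = c(positive = 1, neutral = 0, negative = 0),
              SPAIR1 = c(positive = 0, neutral = 0, negative = 1))
  q_fav <- simulate_qualitative_feedback(st, fav, seed = 12)
  cs2 <- comment_samples(q_fav)
  expect_true(all(cs2$NonFS$GTV$values == 1))
  expect_true(all(cs2$SPAIR1$GTV$values == -1))

  expect_identical(simulate_qualitative_feedback(st, fav, seed = 12), q_fav)
  bad <- list(NonFS = c(0.5, 0.2, 0.2), SPAIR1 = c(1, 0, 0))
  expect_error(simulate_qualitative_feedback(st, bad), "summing to 1")
})

test_that("study export and manifest reload reproduce the masks", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config(seed = 7, n_subjects = 1, n_observers = 2)
  st <- generate_phantom(cfg)
  q <- simulate_qualitative_feedback(st, seed = 8)
  man <- write_phantom_study(st, dir, qualitative = q)
  expect_true(file.exists(man))
  reread <- read_study_manifest(man)
  expect_identical(reread$observer_masks$P01$NonFS$GTV$O1$voxels,
                   st$observer_masks$P01$NonFS$GTV$O1$voxels)
  expect_equal(reread$volumes$P01$SPAIR1$intensities,
               st$volumes$P01$SPAIR1$intensities, tolerance = 1e-6)
  q2 <- read_qualitative_csv(file.path(dir, "qualitative.csv"))
  expect_equal(nrow(q2), nrow(q))
})

test_that("sample-size bookkeeping follows the study design formulas", {
  cfg <- tiny_phantom_config(seed = 13, n_subjects = 2, n_observers = 3)
  st <- generate_phantom(cfg)
  q <- simulate_qualitative_feedback(st, seed = 14)
  samples <- compute_metric_samples(st, q)

  # SNR/CNR: one value per subject
  expect_equal(length(samples$snr$GTV$NonFS$values), 2)
  expect_equal(length(samples$fat_snr$fat$NonFS$values), 2)
  # grades: observers x subjects (x2 sides for bilateral structures)
  expect_equal(length(samples$grade$GTV$NonFS$values), 6)
  expect_equal(length(samples$comment$GTV$NonFS$values), 2)
  # pairwise: ~0.9 x subjects x C(observers, 2) per side
  n_pair_gtv <- length(samples$dsc$GTV$NonFS$values)
  expect_lte(abs(n_pair_gtv - 0.9 * 2 * choose(3, 2)), 1)
  n_pair_par <- length(samples$dsc$parotid$NonFS$values)
  expect_lte(abs(n_pair_par - 0.9 * 2 * 2 * choose(3, 2)), 1)
  # conspicuity: ~0.9 x raw slice count
  raw <- 0
  for (subj in c("P01", "P02")) {
    vol <- st$volumes[[subj]]$NonFS
    for (ob in names(st$observer_masks[[subj]]$NonFS$GTV))
      raw <- raw + nrow(conspicuity_slices(
        vol, st$observer_masks[[subj]]$NonFS$GTV[[ob]]))
  }
  expect_lte(abs(length(samples$conspicuity$GTV$NonFS$values) - 0.9 * raw),
             2)
})
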