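#' Configuration for the digital phantom study
#'
#' Builds the parameter set for a synthetic multi-sequence, multi-observer
#' study with known ground truth. The default geometry is a cuboid of soft
#' tissue holding axis-aligned ellipsoids for the tumour (GTV), two
#' metastatic lymph nodes, two parotid glands and two pterygoid muscles, two
#' lateral fat pads, and a tubular air cavity (trachea stand-in) used as the
#' noise ROI. Default study bookkeeping mirrors a typical sequence-selection
#' study: 4 candidate sequences, 5 subjects, 5 observers.
#'
#' Intensities are generated as `tissue mean + N(0, noise SD)` per sequence;
#' the fat mean of each sequence is multiplied by that sequence's
#' fat-suppression factor (1 = no suppression). Observer contours derive from
#' ground truth by a random isotropic dilation/erosion (radius uniform in
#' `[-jitter_radius_mm, jitter_radius_mm]`) plus a random translation
#' (per-axis Gaussian, SD `jitter_translation_sd_mm`).
#'
#' @param grid_dim integer length-3 voxel grid.
#' @param spacing_mm voxel size in mm.
#' @param sequences character vector of sequence ids.
#' @param n_subjects,n_observers study size.
#' @param structure_means named numeric: mean signal per delineated structure
#'   (GTV, lymph nodes, parotids, pterygoids).
#' @param background_mean mean of unclassified soft tissue.
#' @param fat_mean unsuppressed fat mean signal.
#' @param fat_suppression named numeric, one factor in `[0, 1]` per sequence.
#' @param contrast_scale named numeric, per-sequence multiplier applied to
#'   every non-fat tissue's deviation from the background mean (1 = default
#'   contrast); controls structure-to-surround contrast per sequence.
#' @param noise_sd named numeric (or scalar), additive Gaussian noise SD per
#'   sequence.
#' @param jitter_radius_mm,jitter_translation_sd_mm observer contour jitter.
#' @param seed integer; all randomness in the study flows from it.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(48, 48, 30),
                           spacing_mm = c(2, 2, 2),
                           sequences = c("NonFS", "SPAIR1", "SPAIR3",
                                         "SPAIR4"),
                           n_subjects = 5, n_observers = 5,
                           structure_means = c(GTV = 300, lymph_nodes = 280,
                                               parotid_L = 250,
                                               parotid_R = 250,
                                               pterygoid_L = 120,
                                               pterygoid_R = 120),
                           background_mean = 150,
                           fat_mean = 420,
                           fat_suppression = NULL,
                           contrast_scale = NULL,
                           noise_sd = 12,
                           jitter_radius_mm = 1.5,
                           jitter_translation_sd_mm = 0.75,
                           seed = 1L) {
  if (is.null(fat_suppression))
    fat_suppression <- setNames(
      c(1, rep(0.08, length(sequences) - 1))[seq_along(sequences)],
      sequences)
  if (is.null(contrast_scale))
    contrast_scale <- setNames(rep(1, length(sequences)), sequences)
  if (length(noise_sd) == 1L)
    noise_sd <- setNames(rep(noise_sd, length(sequences)), sequences)
  stopifnot(all(sequences %in% names(fat_suppression)),
            all(sequences %in% names(noise_sd)),
            all(sequences %in% names(contrast_scale)))
  if (any(noise_sd <= 0)) stop("noise SD must be positive")
  if (any(structure_means < 0) || background_mean < 0 || fat_mean < 0)
    stop("tissue means must be non-negative")
  cfg <- list(grid_dim = as.integer(grid_dim), spacing_mm = spacing_mm,
              sequences = sequences, n_subjects = n_subjects,
              n_observers = n_observers, structure_means = structure_means,
              background_mean = background_mean, fat_mean = fat_mean,
              fat_suppression = fat_suppression[sequences],
              contrast_scale = contrast_scale[sequences],
              noise_sd = noise_sd[sequences],
              jitter_radius_mm = jitter_radius_mm,
              jitter_translation_sd_mm = jitter_translation_sd_mm,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_geometry(cfg)
  cfg
}

# Region label array for the phantom geometry; checks the delineated
# structures against the air cavity.
phantom_regions <- function(cfg) {
  d <- cfg$grid_dim; sp <- cfg$spacing_mm
  ext <- d * sp                    # physical extent in mm
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - 0.5) * sp[k]))
  ellipsoid <- function(center_frac, radii_mm) {
    cx <- center_frac * ext
    outer3 <- array(FALSE, d)
    dx2 <- ((ax[[1]] - cx[1]) / radii_mm[1])^2
    dy2 <- ((ax[[2]] - cx[2]) / radii_mm[2])^2
    dz2 <- ((ax[[3]] - cx[3]) / radii_mm[3])^2
    outer3 <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    outer3
  }
  cylinder_z <- function(center_frac, radius_mm, z_frac) {
    cx <- center_frac * ext[1:2]
    dx2 <- outer((ax[[1]] - cx[1])^2, (ax[[2]] - cx[2])^2, "+")
    disk <- dx2 <= radius_mm^2
    zin <- ax[[3]] >= z_frac[1] * ext[3] & ax[[3]] <= z_frac[2] * ext[3]
    array(outer(disk, zin, "&"), d)
  }
  regions <- list(
    GTV         = ellipsoid(c(0.50, 0.32, 0.45), c(14, 14, 14)),
    lymph_nodes = ellipsoid(c(0.30, 0.55, 0.38), c(8, 8, 8)) |
                  ellipsoid(c(0.70, 0.55, 0.38), c(8, 8, 8)),
    parotid_L   = ellipsoid(c(0.16, 0.62, 0.62), c(10, 10, 12)),
    parotid_R   = ellipsoid(c(0.84, 0.62, 0.62), c(10, 10, 12)),
    pterygoid_L = ellipsoid(c(0.30, 0.30, 0.72), c(8, 8, 11)),
    pterygoid_R = ellipsoid(c(0.70, 0.30, 0.72), c(8, 8, 11)),
    fat         = ellipsoid(c(0.12, 0.26, 0.35), c(7, 9, 10)) |
                  ellipsoid(c(0.88, 0.26, 0.35), c(7, 9, 10)),
    noise       = cylinder_z(c(0.50, 0.72), 5, c(0.25, 0.75))
  )
  regions
}

validate_phantom_geometry <- function(cfg) {
  regions <- phantom_regions(cfg)
  nms <- names(regions)
  for (i in seq_along(nms)) {
    if (!any(regions[[nms[i]]]))
      stop("phantom geometry error: region '", nms[i],
           "' is empty on this grid")
    for (j in seq_along(nms))
      if (i < j && any(regions[[nms[i]]] & regions[[nms[j]]]))
        stop("phantom geometry error: regions '", nms[i], "' and '",
             nms[j], "' overlap at this grid size")
  }
  invisible(TRUE)
}

#' Generate a phantom study
#'
#' Builds, for every subject, one [volume_image()] per sequence plus
#' ground-truth masks, simulated per-observer masks for each delineated
#' structure on each sequence, and single-observer reference masks for fat
#' and noise. Identical seeds give identical studies.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `phantom_study` with elements
#'   `volumes[[subject]][[sequence]]`, `truth_masks[[subject]][[structure]]`,
#'   `observer_masks[[subject]][[sequence]][[structure]][[observer]]`
#'   (delineated structures only; `fat` and `noise` appear with the single
#'   observer `"ref"`), and `config`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  regions <- phantom_regions(cfg)
  delineated <- setdiff(names(regions), c("fat", "noise"))
  subjects <- sprintf("P%02d", seq_len(cfg$n_subjects))
  observers <- sprintf("O%d", seq_len(cfg$n_observers))
  set.seed(cfg$seed)

  study <- list(volumes = list(), truth_masks = list(),
                observer_masks = list(), config = cfg)
  for (subj in subjects) {
    study$truth_masks[[subj]] <- lapply(names(regions), function(nm)
      structure_mask(regions[[nm]], cfg$spacing_mm, nm, "truth", subj,
                     "all"))
    names(study$truth_masks[[subj]]) <- names(regions)
    for (sq in cfg$sequences) {
      mean_map <- array(cfg$background_mean, cfg$grid_dim)
      cs <- cfg$contrast_scale[[sq]]
      for (nm in delineated)
        mean_map[regions[[nm]]] <- cfg$background_mean +
          cs * (cfg$structure_means[[nm]] - cfg$background_mean)
      mean_map[regions$fat] <- cfg$fat_mean * cfg$fat_suppression[[sq]]
      mean_map[regions$noise] <- 0
      vox <- mean_map + rnorm(length(mean_map), 0, cfg$noise_sd[[sq]])
      study$volumes[[subj]][[sq]] <-
        volume_image(array(vox, cfg$grid_dim), cfg$spacing_mm, sq, subj)
      for (nm in delineated) {
        truth <- structure_mask(regions[[nm]], cfg$spacing_mm, nm, "truth",
                                subj, sq)
        oms <- simulate_observer_masks(
          truth, jitter_radius_mm = cfg$jitter_radius_mm,
          translation_sd_mm = cfg$jitter_translation_sd_mm,
          n_observers = cfg$n_observers)
        names(oms) <- observers
        for (ob in observers) oms[[ob]]$observer_id <- ob
        study$observer_masks[[subj]][[sq]][[nm]] <- oms
      }
      for (nm in c("fat", "noise"))
        study$observer_masks[[subj]][[sq]][[nm]] <- list(
          ref = structure_mask(regions[[nm]], cfg$spacing_mm, nm, "ref",
                               subj, sq))
    }
  }
  class(study) <- "phantom_study"
  study
}

#' Simulate observer contours by jittering a ground-truth mask
#'
#' Each observer's mask is the truth isotropically dilated or eroded by a
#' radius drawn uniformly from `[-jitter_radius_mm, jitter_radius_mm]` and
#' then shifted by a per-axis Gaussian translation (SD
#' `translation_sd_mm`, rounded to whole voxels). An erosion or shift that
#' would empty the mask is retried with the radius halved (and finally the
#' unjittered truth), with a warning. Zero jitter reproduces the truth for
#' every observer.
#'
#' Randomness comes from the current RNG stream; seed it (or call from
#' [generate_phantom()], which seeds once for the whole study) for
#' reproducibility.
#'
#' @param truth a non-empty [structure_mask()].
#' @param jitter_radius_mm maximum absolute dilation/erosion radius.
#' @param translation_sd_mm per-axis translation SD in mm.
#' @param n_observers number of observer masks to simulate.
#' @param seed optional integer; when given, sets the RNG seed first.
#' @return list of `n_observers` [structure_mask()]s.
#' @export
simulate_observer_masks <- function(truth, jitter_radius_mm = 1.5,
                                    translation_sd_mm = 0.75,
                                    n_observers = 5, seed = NULL) {
  stop_if_empty(truth, "truth mask")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_observers)
  for (i in seq_len(n_observers)) {
    r <- if (jitter_radius_mm > 0)
      runif(1, -jitter_radius_mm, jitter_radius_mm) else 0
    shift_mm <- if (translation_sd_mm > 0)
      rnorm(3, 0, translation_sd_mm) else c(0, 0, 0)
    shift_vox <- as.integer(round(shift_mm / truth$spacing_mm))
    m <- jittered_mask(truth, r, shift_vox)
    while (mask_is_empty(m) && abs(r) > 1e-3) {
      r <- r / 2
      warning("observer jitter emptied a mask; retrying with radius ",
              signif(r, 3), " mm", call. = FALSE)
      m <- jittered_mask(truth, r, shift_vox)
    }
    if (mask_is_empty(m)) m <- truth
    out[[i]] <- m
  }
  out
}

jittered_mask <- function(truth, radius_mm, shift_vox) {
  m <- if (abs(radius_mm) < 1e-12) truth else morph_mask(truth, radius_mm)
  if (any(shift_vox != 0) && !mask_is_empty(m))
    m$voxels <- shift_array(m$voxels, shift_vox)
  m
}

shift_array <- function(a, shift) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { src[[k]] <- 1:(d[k] - s); dst[[k]] <- (1 + s):d[k] }
    else        { src[[k]] <- (1 - s):d[k]; dst[[k]] <- 1:(d[k] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Simulate the qualitative feedback table for a phantom study
#'
#' For every (observer, subject, structure), the observer ranks the sequences
#' by a noisy favourability draw (rank 1 = most preferred) and leaves one
#' comment per sequence drawn from that sequence's
#' positive/neutral/negative probabilities.
#'
#' @param study a `phantom_study`.
#' @param favorability named list (by sequence) of length-3 probability
#'   vectors `(positive, neutral, negative)` summing to 1; default all
#'   neutral.
#' @param grade_noise_sd SD of the Gaussian noise added to each sequence's
#'   favourability score (positive minus negative probability) before
#'   ranking; default 0.5.
#' @param seed optional integer RNG seed.
#' @return qualitative records data frame (see [read_qualitative_csv()]).
#' @export
simulate_qualitative_feedback <- function(study, favorability = NULL,
                                          grade_noise_sd = 0.5,
                                          seed = NULL) {
  cfg <- study$config
  if (!is.null(seed)) set.seed(seed)
  if (is.null(favorability))
    favorability <- setNames(
      rep(list(c(positive = 0, neutral = 1, negative = 0)),
          length(cfg$sequences)), cfg$sequences)
  for (sq in cfg$sequences) {
    p <- favorability[[sq]]
    if (length(p) != 3 || abs(sum(p) - 1) > 1e-8)
      stop("favorability for '", sq,
           "' must be 3 probabilities summing to 1")
  }
  subjects <- names(study$volumes)
  observers <- sprintf("O%d", seq_len(cfg$n_observers))
  structures <- setdiff(names(study$truth_masks[[subjects[1]]]),
                        c("fat", "noise"))
  cats <- c("positive", "neutral", "negative")
  rows <- list()
  for (subj in subjects) for (ob in observers) for (st in structures) {
    util <- vapply(cfg$sequences, function(sq) {
      p <- favorability[[sq]]
      (p[1] - p[3]) + rnorm(1, 0, grade_noise_sd)
    }, numeric(1))
    grade <- rank(-util, ties.method = "first")  # 1 = most preferred
    for (k in seq_along(cfg$sequences)) {
      sq <- cfg$sequences[k]
      cm <- sample(cats, 1, prob = favorability[[sq]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, sequence_id = sq, structure_label = st,
        observer_id = ob, grade = grade[k], comment = cm)
    }
  }
  do.call(rbind, rows)
}

#' Write a phantom study to disk
#'
#' Emits NIfTI volumes and masks, a manifest CSV mapping every file to its
#' (subject, sequence, structure, observer) role, and optionally the
#' qualitative CSV.
#'
#' @param study a `phantom_study`.
#' @param dir output directory (created if needed).
#' @param qualitative optional qualitative records data frame.
#' @return the manifest path, invisibly.
#' @export
write_phantom_study <- function(study, dir, qualitative = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(file, kind, subj, sq, st = NA, ob = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, kind = kind, subject_id = subj, sequence_id = sq,
      structure_label = st, observer_id = ob)
  for (subj in names(study$volumes)) {
    for (sq in names(study$volumes[[subj]])) {
      f <- sprintf("%s_%s_volume.nii.gz", subj, sq)
      write_nifti_object(study$volumes[[subj]][[sq]], file.path(dir, f))
      add(f, "volume", subj, sq)
      for (st in names(study$observer_masks[[subj]][[sq]])) {
        oms <- study$observer_masks[[subj]][[sq]][[st]]
        for (ob in names(oms)) {
          f <- sprintf("%s_%s_%s_%s_mask.nii.gz", subj, sq, st, ob)
          write_nifti_object(oms[[ob]], file.path(dir, f))
          add(f, "mask", subj, sq, st, ob)
        }
      }
    }
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  write.csv(man, man_path, row.names = FALSE)
  if (!is.null(qualitative))
    write.csv(qualitative, file.path(dir, "qualitative.csv"),
              row.names = FALSE)
  invisible(man_path)
}
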