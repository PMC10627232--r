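#' Slice-wise conspicuity of a structure
#'
#' Conspicuity measures structure visibility as the ratio of ROI contrast to
#' the complexity of the surrounding signal, evaluated per axial slice. The
#' formulation used here is built from the four standard 1 and 2 mm
#' morphological variants of the observer's mask:
#'
#' * core = the mask contracted by 1 mm (a guard band against
#'   partial-volume voxels on the boundary);
#' * surround ring = the 2 mm expansion minus the 1 mm expansion;
#' * contrast = |mean(core) - mean(ring)| on the slice;
#' * complexity = sample SD of the ring intensities on the slice;
#' * conspicuity = contrast / complexity.
#'
#' Masks are morphed in 3D (spacing-aware) while the ratio is evaluated in 2D
#' per slice, the plane the structures are delineated in. The formulation is
#' deliberately isolated in this one function so alternative contrast /
#' complexity readings can be swapped without touching the pipeline.
#'
#' @param volume a [volume_image()].
#' @param family a [mask_family()] built from one observer's mask.
#' @param slice_index 1-based axial slice index.
#' @param eps_floor complexity floor; slices whose ring SD falls below it
#'   return `contrast / eps_floor` flagged as capped. Default
#'   `1e-6 * diff(range(volume))`.
#' @return scalar conspicuity, or `NA` (skipped-slice sentinel) when the core
#'   or the ring is empty or has fewer than 2 ring voxels on that slice.
#'   A capped value carries attribute `capped = TRUE`.
#' @export
slice_conspicuity <- function(volume, family, slice_index,
                              eps_floor = NULL) {
  stopifnot(inherits(family, "mask_family"))
  core <- family$contracted[[1]]$voxels[, , slice_index]
  ring <- family$expanded[[2]]$voxels[, , slice_index] &
          !family$expanded[[1]]$voxels[, , slice_index]
  if (!any(core) || sum(ring) < 2L) return(NA_real_)
  img <- volume$intensities[, , slice_index]
  contrast <- abs(mean(img[core]) - mean(img[ring]))
  complexity <- sd(img[ring])
  if (is.null(eps_floor))
    eps_floor <- 1e-6 * diff(range(volume$intensities))
  if (eps_floor <= 0) eps_floor <- .Machine$double.eps
  if (complexity < eps_floor) {
    out <- contrast / eps_floor
    attr(out, "capped") <- TRUE
    return(out)
  }
  contrast / complexity
}

#' Conspicuity values over all occupied slices of one mask
#'
#' Computes [slice_conspicuity()] on every axial slice the original mask
#' occupies and returns the valid per-slice values with their slice indices.
#'
#' @inheritParams slice_conspicuity
#' @param mask a non-empty [structure_mask()] (one observer).
#' @param distances_mm morphology distances forwarded to [mask_family()].
#' @return data frame with columns `slice` and `value` (skipped slices
#'   omitted).
#' @export
conspicuity_slices <- function(volume, mask, distances_mm = c(1, 2),
                               eps_floor = NULL) {
  stop_if_empty(mask)
  check_same_grid(mask, volume)
  fam <- mask_family(mask, distances_mm)
  occupied <- which(apply(mask$voxels, 3, any))
  if (is.null(eps_floor))
    eps_floor <- 1e-6 * diff(range(volume$intensities))
  vals <- vapply(occupied, function(s)
    as.numeric(slice_conspicuity(volume, fam, s, eps_floor)), numeric(1))
  ok <- !is.na(vals)
  data.frame(slice = occupied[ok], value = vals[ok])
}

#' Pooled, filtered conspicuity sample for a sequence-structure pair
#'
#' Per-slice conspicuity values from every observer's mask on every subject
#' are stacked (tagged with subject, observer and slice), then trimmed to the
#' inner percentile band with [pool_and_filter()]. The expected sample size is
#' therefore about `inner_fraction x slices x subjects x observers`.
#'
#' @param volumes list of [volume_image()]s, one per subject (named by
#'   subject).
#' @param masks_by_subject list (by subject) of lists (by observer) of
#'   [structure_mask()]s.
#' @param inner_fraction passed to [pool_and_filter()].
#' @param distances_mm,eps_floor passed to [conspicuity_slices()].
#' @return a filtered [metric_sample()].
#' @export
conspicuity_series <- function(volumes, masks_by_subject,
                               inner_fraction = 0.90,
                               distances_mm = c(1, 2), eps_floor = NULL) {
  vals <- numeric(0)
  prov <- list()
  seq_id <- NULL; struct <- NULL
  for (subj in names(masks_by_subject)) {
    vol <- volumes[[subj]]
    for (obs in names(masks_by_subject[[subj]])) {
      m <- masks_by_subject[[subj]][[obs]]
      if (mask_is_empty(m)) next
      seq_id <- m$sequence_id; struct <- m$structure_label
      sl <- conspicuity_slices(vol, m, distances_mm, eps_floor)
      if (nrow(sl) == 0L) next
      vals <- c(vals, sl$value)
      prov[[length(prov) + 1L]] <- data.frame(
        subject_id = subj, observer_id = obs, slice = sl$slice)
    }
  }
  if (length(vals) == 0L)
    stop("no valid conspicuity slice for this sequence-structure pair")
  sample <- metric_sample("conspicuity", seq_id, struct, vals,
                          do.call(rbind, prov))
  pool_and_filter(sample, inner_fraction)
}
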