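#' Noise standard deviation from an air-cavity segmentation
#'
#' The noise level of a volume is estimated as the sample standard deviation
#' (denominator n-1) of the intensities under the noise mask — in the
#' intended workflow an air-filled cavity (e.g. ten axial slices of the
#' trachea), used because the background outside the patient is masked in
#' postprocessing.
#'
#' @param volume a [volume_image()].
#' @param noise_mask a non-empty [structure_mask()] on the same grid.
#' @return positive scalar noise SD.
#' @export
noise_sd <- function(volume, noise_mask) {
  stop_if_empty(noise_mask, "noise mask")
  check_same_grid(noise_mask, volume)
  v <- volume$intensities[noise_mask$voxels]
  if (length(v) < 2L)
    stop("noise mask must cover at least 2 voxels")
  s <- sd(v)
  if (s == 0)
    stop("degenerate noise ROI: all noise voxels identical (SD = 0)")
  s
}

#' Signal-to-noise ratio of a sequence-structure pair
#'
#' Mean signal of the structure divided by the noise SD. With several
#' observers, every observer's ROI voxels contribute to the mean (the mean is
#' taken over all (observer, voxel) samples), so duplicated identical masks
#' leave the SNR unchanged.
#'
#' @param volume a [volume_image()].
#' @param structure_masks a single [structure_mask()] or a list of per-observer
#'   masks; empty masks are dropped, but at least one non-empty mask is
#'   required.
#' @param noise_mask noise segmentation passed to [noise_sd()].
#' @return scalar SNR.
#' @export
snr <- function(volume, structure_masks, noise_mask) {
  vals <- pooled_roi_values(volume, structure_masks)
  mean(vals) / noise_sd(volume, noise_mask)
}

#' Contrast-to-noise ratio between two structures
#'
#' The signed difference of the two structures' SNRs on the same volume,
#' `snr(masks_a) - snr(masks_b)`; antisymmetric in its arguments. Typical
#' references for `masks_b` are the fat segmentation and the pterygoid
#' muscle.
#'
#' @inheritParams snr
#' @param masks_a,masks_b mask or list of per-observer masks for the
#'   structure and the reference.
#' @return scalar CNR.
#' @export
cnr <- function(volume, masks_a, masks_b, noise_mask) {
  snr(volume, masks_a, noise_mask) - snr(volume, masks_b, noise_mask)
}

pooled_roi_values <- function(volume, masks) {
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  masks <- Filter(function(m) !mask_is_empty(m), masks)
  if (length(masks) == 0L)
    stop("all structure masks are empty")
  vals <- unlist(lapply(masks, function(m) {
    check_same_grid(m, volume)
    volume$intensities[m$voxels]
  }))
  vals
}
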