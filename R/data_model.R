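#' Construct a volume image
#'
#' A `volume_image` is a 3D scalar intensity grid with physical voxel spacing,
#' tagged with the sequence and subject it was acquired for. Intensities must
#' be finite; spacing components must be positive.
#'
#' @param intensities numeric 3D array (arbitrary signal units).
#' @param spacing_mm numeric length-3 vector of voxel sizes in mm, one per axis
#'   (x, y, axial slice).
#' @param sequence_id,subject_id character identifiers.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(intensities, spacing_mm, sequence_id = "seq",
                         subject_id = "subj") {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array, got ",
         length(dim(intensities)), " dimensions")
  if (!all(is.finite(intensities)))
    stop("volume contains non-finite voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite values")
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         sequence_id = as.character(sequence_id),
         subject_id = as.character(subject_id)),
    class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s / %s  %s voxels @ %s mm\n",
              x$subject_id, x$sequence_id,
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' Construct a binary structure mask
#'
#' A `structure_mask` lives on the same voxel lattice as its paired
#' [volume_image()] and is tagged with a structure label and the observer who
#' delineated it. Any nonzero voxel is treated as inside the mask. Empty masks
#' are tolerated at construction (flagged via [mask_is_empty()]) but rejected
#' by every metric computation.
#'
#' @param voxels logical/numeric 3D array; nonzero means inside.
#' @param spacing_mm numeric length-3 voxel size in mm.
#' @param structure_label structure name (e.g. `"GTV"`, `"parotid_L"`,
#'   `"fat"`, `"noise"`).
#' @param observer_id,subject_id,sequence_id character identifiers.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, spacing_mm, structure_label,
                           observer_id = "obs", subject_id = "subj",
                           sequence_id = "seq") {
  if (length(dim(voxels)) != 3L)
    stop("mask must be a 3D array")
  v <- array(as.logical(voxels != 0), dim = dim(voxels))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(
    list(voxels = v, spacing_mm = spacing_mm,
         structure_label = as.character(structure_label),
         observer_id = as.character(observer_id),
         subject_id = as.character(subject_id),
         sequence_id = as.character(sequence_id)),
    class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s / %s / %s / %s  %d voxels\n",
              x$subject_id, x$sequence_id, x$structure_label, x$observer_id,
              sum(x$voxels)))
  invisible(x)
}

#' @rdname structure_mask
#' @param mask a `structure_mask`.
#' @export
mask_is_empty <- function(mask) !any(mask$voxels)

check_same_grid <- function(mask, ref, what = "volume") {
  rdim <- if (inherits(ref, "volume_image")) dim(ref$intensities)
          else dim(ref$voxels)
  rsp <- ref$spacing_mm
  if (!identical(dim(mask$voxels), rdim))
    stop(sprintf("mask grid %s does not match %s grid %s",
                 paste(dim(mask$voxels), collapse = "x"), what,
                 paste(rdim, collapse = "x")))
  if (!isTRUE(all.equal(mask$spacing_mm, rsp, tolerance = 1e-6)))
    stop("mask voxel spacing does not match ", what, " spacing")
  invisible(TRUE)
}

stop_if_empty <- function(mask, what = "mask") {
  if (mask_is_empty(mask))
    stop(sprintf("%s (%s/%s/%s) is empty; metrics require a non-empty mask",
                 what, mask$subject_id, mask$sequence_id,
                 mask$structure_label))
  invisible(TRUE)
}

#' Bundle per-observer masks for one sequence-structure pair
#'
#' A sequence-structure pair is one anatomical structure as segmented on one
#' candidate sequence for one subject; it is the unit of all metric
#' computation. All masks must share subject, sequence, and structure tags.
#'
#' @param masks list of [structure_mask()] objects, one per observer.
#' @return object of class `sequence_structure_pair`.
#' @export
sequence_structure_pair <- function(masks) {
  if (length(masks) < 1L) stop("at least one observer mask required")
  tags <- vapply(masks, function(m)
    paste(m$subject_id, m$sequence_id, m$structure_label, sep = "\r"),
    character(1))
  if (length(unique(tags)) != 1L)
    stop("all masks of a sequence-structure pair must share subject, ",
         "sequence and structure tags")
  structure(
    list(masks = masks,
         subject_id = masks[[1]]$subject_id,
         sequence_id = masks[[1]]$sequence_id,
         structure_label = masks[[1]]$structure_label),
    class = "sequence_structure_pair")
}

#' Construct a metric sample
#'
#' Pooled per-(sequence, structure) metric values with per-value provenance
#' (subject, observer or observer pair, slice) and a flag recording whether
#' the inner-percentile outlier filter has been applied.
#'
#' @param metric_name metric identifier, e.g. `"conspicuity"`.
#' @param sequence_id,structure_label grouping tags.
#' @param values numeric vector of finite metric values.
#' @param provenance data frame with one row per value (columns such as
#'   `subject_id`, `observer_id`, `slice`); defaults to row indices.
#' @param filtered logical; `TRUE` once [pool_and_filter()] has run.
#' @return object of class `metric_sample`.
#' @export
metric_sample <- function(metric_name, sequence_id, structure_label, values,
                          provenance = NULL, filtered = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("metric values must be finite")
  if (is.null(provenance))
    provenance <- data.frame(index = seq_along(values))
  if (nrow(provenance) != length(values))
    stop("provenance must have one row per value")
  structure(
    list(metric_name = metric_name, sequence_id = sequence_id,
         structure_label = structure_label, values = values,
         provenance = provenance, filtered = isTRUE(filtered)),
    class = "metric_sample")
}

#' @export
print.metric_sample <- function(x, ...) {
  cat(sprintf("<metric_sample> %s | %s | %s : n=%d%s\n", x$metric_name,
              x$sequence_id, x$structure_label, length(x$values),
              if (x$filtered) " (filtered)" else ""))
  invisible(x)
}

#' Trim a sample to its inner percentile band
#'
#' Outlier handling applied to pooled slice-wise and pairwise metric stacks:
#' values are restricted to the symmetric inner band of the empirical
#' distribution (default the inner 90%, i.e. the closed \[5th, 95th\]
#' percentile interval, linear-interpolation percentiles). Survivor order is
#' preserved. Applied to a [metric_sample()] the operation is idempotent:
#' a sample already flagged `filtered` is returned unchanged.
#'
#' @param x numeric vector or [metric_sample()].
#' @param inner_fraction fraction of the distribution to keep (default 0.90).
#' @return same type as `x`; for a `metric_sample`, provenance rows of
#'   trimmed values are dropped and `filtered` is set.
#' @export
#' @examples
#' pool_and_filter(1:100)        # keeps 6..95
pool_and_filter <- function(x, inner_fraction = 0.90) {
  UseMethod("pool_and_filter")
}

#' @export
pool_and_filter.numeric <- function(x, inner_fraction = 0.90) {
  if (length(x) == 0L) stop("cannot filter an empty sample")
  if (any(!is.finite(x))) stop("sample contains non-finite values")
  if (inner_fraction <= 0 || inner_fraction > 1)
    stop("inner_fraction must be in (0, 1]")
  x[filter_keep_index(x, inner_fraction)]
}

#' @export
pool_and_filter.metric_sample <- function(x, inner_fraction = 0.90) {
  if (x$filtered) return(x)
  keep <- filter_keep_index(x$values, inner_fraction)
  metric_sample(x$metric_name, x$sequence_id, x$structure_label,
                x$values[keep], x$provenance[keep, , drop = FALSE],
                filtered = TRUE)
}

filter_keep_index <- function(values, inner_fraction) {
  tail_frac <- (1 - inner_fraction) / 2
  bounds <- quantile(values, c(tail_frac, 1 - tail_frac),
                     type = 7, names = FALSE)
  which(values >= bounds[1] & values <= bounds[2])
}
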