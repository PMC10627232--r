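#' Dice similarity coefficient of two masks
#'
#' Volumetric overlap `2|A n B| / (|A| + |B|)` where `|A|` and `|B|` count
#' mask voxels; ranges from 0 (no overlap) to 1 (perfect overlap) and is
#' symmetric in its arguments.
#'
#' @param a,b [structure_mask()]s on the same grid; at least one non-empty.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, what = "second mask")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) stop("both masks are empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' 95th-percentile Hausdorff distance between two masks (mm)
#'
#' Surface agreement: for each surface voxel of A the minimum Euclidean
#' distance in mm to B's surface is recorded (and vice versa), and the 95th
#' percentile of the concatenated bidirectional distance vector is returned.
#' Surface voxels are mask voxels with at least one face neighbour outside
#' the mask; distances use voxel centres and physical spacing; the percentile
#' interpolates linearly between order statistics. Identical masks give 0;
#' smaller values mean better agreement.
#'
#' @param a,b non-empty [structure_mask()]s on the same grid.
#' @param probability percentile level, default 0.95 (1 gives the classical
#'   Hausdorff distance).
#' @return scalar distance in mm.
#' @export
hausdorff95 <- function(a, b, probability = 0.95) {
  check_same_grid(a, b, what = "second mask")
  stop_if_empty(a); stop_if_empty(b)
  box <- mask_bbox(a$voxels | b$voxels)
  sa <- surface_voxels(a$voxels[box[[1]], box[[2]], box[[3]], drop = FALSE])
  sb <- surface_voxels(b$voxels[box[[1]], box[[2]], box[[3]], drop = FALSE])
  da <- distance_map(sb, a$spacing_mm)[sa]   # A-surface -> B-surface
  db <- distance_map(sa, b$spacing_mm)[sb]   # B-surface -> A-surface
  quantile(c(da, db), probability, type = 7, names = FALSE)
}

# All-pairs Dice and HD95 for a list of non-empty masks on one grid.
# Each mask's surface distance field is computed once (on the padded union
# bounding box) and shared across its pairings.
pairwise_surface_metrics <- function(masks, probability = 0.95) {
  n <- length(masks)
  stopifnot(n >= 2L)
  sp <- masks[[1]]$spacing_mm
  union_vox <- Reduce(`|`, lapply(masks, function(m) m$voxels))
  box <- mask_bbox(union_vox)
  vox <- lapply(masks, function(m)
    m$voxels[box[[1]], box[[2]], box[[3]], drop = FALSE])
  surf <- lapply(vox, surface_voxels)
  dmap <- lapply(surf, function(s) distance_map(s, sp))
  counts <- vapply(vox, sum, numeric(1))
  idx <- combn(n, 2)
  out <- data.frame(i = idx[1, ], j = idx[2, ], dsc = NA_real_,
                    hd95 = NA_real_)
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    out$dsc[k] <- 2 * sum(vox[[i]] & vox[[j]]) / (counts[i] + counts[j])
    out$hd95[k] <- quantile(c(dmap[[j]][surf[[i]]], dmap[[i]][surf[[j]]]),
                            probability, type = 7, names = FALSE)
  }
  out
}

#' Pairwise inter-observer agreement for a sequence-structure pair
#'
#' [dice()] and [hausdorff95()] over all unordered observer pairs, for each
#' subject; values are stacked across subjects and trimmed to the inner
#' percentile band, so each metric's sample size is about
#' `inner_fraction x subjects x choose(observers, 2)`.
#'
#' @param pairs_by_subject list (by subject) of [sequence_structure_pair()]s
#'   (each holding that subject's per-observer masks), or a single
#'   `sequence_structure_pair`.
#' @param inner_fraction passed to [pool_and_filter()].
#' @return list with filtered [metric_sample()]s `dsc` and `hd95`.
#' @export
pairwise_agreement <- function(pairs_by_subject, inner_fraction = 0.90) {
  if (inherits(pairs_by_subject, "sequence_structure_pair"))
    pairs_by_subject <- setNames(list(pairs_by_subject),
                                 pairs_by_subject$subject_id)
  dvals <- numeric(0); hvals <- numeric(0); prov <- list()
  seq_id <- NULL; struct <- NULL
  for (subj in names(pairs_by_subject)) {
    p <- pairs_by_subject[[subj]]
    masks <- Filter(function(m) !mask_is_empty(m), p$masks)
    if (length(masks) < 2L)
      stop("pairwise agreement needs at least 2 non-empty observer masks ",
           "(subject ", subj, ")")
    seq_id <- p$sequence_id; struct <- p$structure_label
    obs <- vapply(masks, function(m) m$observer_id, character(1))
    pm <- pairwise_surface_metrics(masks)
    dvals <- c(dvals, pm$dsc)
    hvals <- c(hvals, pm$hd95)
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = subj,
      observer_pair = paste(obs[pm$i], obs[pm$j], sep = "|"))
  }
  prov <- do.call(rbind, prov)
  list(
    dsc = pool_and_filter(
      metric_sample("dsc", seq_id, struct, dvals, prov), inner_fraction),
    hd95 = pool_and_filter(
      metric_sample("hd95", seq_id, struct, hvals, prov), inner_fraction))
}
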