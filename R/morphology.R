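#' Euclidean distance map to a voxel set
#'
#' Spacing-aware 3D distance transform: for every voxel of the grid, the
#' physical distance in mm (voxel centres as points) to the nearest `TRUE`
#' voxel of `features`. Exact (separable parabola-envelope algorithm), not an
#' approximation.
#'
#' @param features logical 3D array.
#' @param spacing_mm numeric length-3 voxel size in mm.
#' @return numeric 3D array of distances (0 on the feature set, `Inf` if the
#'   feature set is empty).
#' @export
distance_map <- function(features, spacing_mm) {
  d <- dim(features)
  if (length(d) != 3L) stop("features must be a 3D array")
  sq <- edt_cpp(as.logical(features), as.integer(d), as.numeric(spacing_mm))
  array(sqrt(sq), dim = d)
}

# Index ranges of the bounding box of TRUE voxels, padded by margin_vox
# voxels per axis and clamped to the grid. NULL if no TRUE voxel.
mask_bbox <- function(voxels, margin_vox = c(1L, 1L, 1L)) {
  idx <- which(voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  d <- dim(voxels)
  lapply(1:3, function(k) {
    lo <- max(1L, min(idx[, k]) - margin_vox[k])
    hi <- min(d[k], max(idx[, k]) + margin_vox[k])
    lo:hi
  })
}

# Distance map evaluated on the padded bounding box of `features`, returned
# together with the box. Correct for any query voxel inside the box because
# the box contains every feature voxel.
cropped_distance_map <- function(features, spacing_mm, margin_vox) {
  box <- mask_bbox(features, margin_vox)
  if (is.null(box)) return(NULL)
  sub <- features[box[[1]], box[[2]], box[[3]], drop = FALSE]
  list(dist = distance_map(sub, spacing_mm), box = box)
}

#' Isotropically expand or contract a mask by a physical distance
#'
#' Expansion by `d > 0` mm keeps every voxel whose Euclidean distance to the
#' mask is at most `d`; contraction (`d < 0`) keeps the mask voxels whose
#' distance to the mask complement exceeds `|d|`. Distances are 3D and
#' spacing-aware (voxel centres as points), so 1 mm means 1 mm on
#' anisotropic grids too. A contraction that empties the mask is not an
#' error: the empty mask is returned and flagged via [mask_is_empty()].
#'
#' @param mask a [structure_mask()].
#' @param distance_mm signed distance in mm (positive expands, negative
#'   contracts, 0 is the identity).
#' @return a [structure_mask()] on the same grid.
#' @export
morph_mask <- function(mask, distance_mm) {
  stopifnot(inherits(mask, "structure_mask"))
  stop_if_empty(mask)
  if (distance_mm == 0) return(mask)
  out <- mask
  if (distance_mm > 0) {
    margin <- as.integer(ceiling(distance_mm / mask$spacing_mm)) + 1L
    cd <- cropped_distance_map(mask$voxels, mask$spacing_mm, margin)
    vox <- array(FALSE, dim(mask$voxels))
    vox[cd$box[[1]], cd$box[[2]], cd$box[[3]]] <-
      cd$dist <= distance_mm + 1e-7
    out$voxels <- vox
  } else {
    cd <- complement_distance_map(mask)
    if (is.null(cd)) return(out)   # mask fills the whole grid
    keep <- array(FALSE, dim(mask$voxels))
    keep[cd$box[[1]], cd$box[[2]], cd$box[[3]]] <-
      cd$dist > abs(distance_mm) + 1e-7
    out$voxels <- mask$voxels & keep
  }
  out
}

# Distance to the mask complement, evaluated on the mask's padded bounding
# box. Valid at mask voxels: the nearest complement voxel of any mask voxel
# is adjacent to the mask surface and therefore inside the box. When the
# mask fills the whole grid there is no complement and NULL is returned.
complement_distance_map <- function(mask) {
  if (all(mask$voxels)) return(NULL)
  box <- mask_bbox(mask$voxels, c(1L, 1L, 1L))
  sub <- !mask$voxels[box[[1]], box[[2]], box[[3]], drop = FALSE]
  # the mask may fill its own bounding box (flush with the grid edge); the
  # grid outside the box still provides no complement closer than box side
  if (!any(sub)) return(NULL)
  list(dist = distance_map(sub, mask$spacing_mm), box = box)
}

#' Build the morphological mask family used by conspicuity
#'
#' The family holds the original mask together with its contractions and
#' expansions at the configured distances (1 and 2 mm by default). The
#' nesting `contract(2) <= contract(1) <= original <= expand(1) <= expand(2)`
#' holds by construction. The two distance transforms (to the mask and to
#' its complement) are computed once and shared across distances.
#'
#' @param mask a [structure_mask()].
#' @param distances_mm positive distances, default `c(1, 2)`.
#' @return object of class `mask_family` with elements `original`,
#'   `contracted` (list by distance) and `expanded` (list by distance).
#' @export
mask_family <- function(mask, distances_mm = c(1, 2)) {
  stopifnot(inherits(mask, "structure_mask"), all(distances_mm > 0))
  stop_if_empty(mask)
  distances_mm <- sort(distances_mm)
  dmax <- max(distances_mm)
  margin <- as.integer(ceiling(dmax / mask$spacing_mm)) + 1L
  cd_out <- cropped_distance_map(mask$voxels, mask$spacing_mm, margin)
  cd_in <- complement_distance_map(mask)
  blank <- array(FALSE, dim(mask$voxels))
  expand_at <- function(d) {
    vox <- blank
    vox[cd_out$box[[1]], cd_out$box[[2]], cd_out$box[[3]]] <-
      cd_out$dist <= d + 1e-7
    m <- mask; m$voxels <- vox; m
  }
  contract_at <- function(d) {
    m <- mask
    if (is.null(cd_in)) return(m)  # mask fills the whole grid
    keep <- blank
    keep[cd_in$box[[1]], cd_in$box[[2]], cd_in$box[[3]]] <-
      cd_in$dist > d + 1e-7
    m$voxels <- mask$voxels & keep
    m
  }
  key <- sprintf("%gmm", distances_mm)
  contracted <- lapply(distances_mm, contract_at)
  expanded <- lapply(distances_mm, expand_at)
  names(contracted) <- names(expanded) <- key
  structure(list(original = mask, contracted = contracted,
                 expanded = expanded, distances_mm = distances_mm),
            class = "mask_family")
}

#' Surface voxels of a mask
#'
#' A mask voxel is a surface voxel when at least one of its six face
#' neighbours lies outside the mask; the grid boundary counts as outside.
#'
#' @param voxels logical 3D array.
#' @return logical 3D array marking surface voxels.
#' @export
surface_voxels <- function(voxels) {
  d <- dim(voxels)
  if (length(d) != 3L) stop("voxels must be a 3D array")
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- voxels
  inner <- function(sx, sy, sz)
    pad[(2:(d[1] + 1L)) + sx, (2:(d[2] + 1L)) + sy, (2:(d[3] + 1L)) + sz]
  all_nb <- inner(-1, 0, 0) & inner(1, 0, 0) &
            inner(0, -1, 0) & inner(0, 1, 0) &
            inner(0, 0, -1) & inner(0, 0, 1)
  voxels & !all_nb
}
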