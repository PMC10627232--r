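#' Load a 3D volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file, normalises it to a 3D array (trailing
#' singleton dimensions are squeezed), takes voxel spacing from the header,
#' and validates that every voxel is finite.
#'
#' @param path path to a NIfTI file.
#' @param sequence_id,subject_id identifiers attached to the volume.
#' @return a [volume_image()].
#' @export
load_volume <- function(path, sequence_id = "seq", subject_id = "subj") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  arr <- squeeze_to_3d(as.array(img), path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (!all(is.finite(arr)))
    stop("volume '", path, "' contains non-finite voxels")
  volume_image(arr, sp, sequence_id, subject_id)
}

#' Load a binary mask from a NIfTI file
#'
#' Any nonzero voxel is inside the mask. If `volume` is supplied, the mask
#' grid (shape and spacing) is checked against it and a mismatch is an error.
#' Empty masks load with a warning and are rejected later by metric
#' computations.
#'
#' @param path path to a NIfTI file.
#' @param structure_label,observer_id,subject_id,sequence_id identifiers.
#' @param volume optional [volume_image()] the mask must be registered to.
#' @return a [structure_mask()].
#' @export
load_mask <- function(path, structure_label, observer_id = "obs",
                      subject_id = "subj", sequence_id = "seq",
                      volume = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI mask '", path, "': ",
                         conditionMessage(e)))
  arr <- squeeze_to_3d(as.array(img), path)
  arr[!is.finite(arr)] <- 0
  sp <- RNifti::pixdim(img)[seq_len(3)]
  m <- structure_mask(arr, sp, structure_label, observer_id, subject_id,
                      sequence_id)
  if (!is.null(volume)) check_same_grid(m, volume)
  if (mask_is_empty(m))
    warning("mask '", path, "' is empty", call. = FALSE)
  m
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [volume_image()] or [structure_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_object <- function(x, path) {
  arr <- if (inherits(x, "volume_image")) x$intensities
         else if (inherits(x, "structure_mask")) array(as.integer(x$voxels),
                                                       dim = dim(x$voxels))
         else stop("x must be a volume_image or structure_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

squeeze_to_3d <- function(arr, path) {
  d <- dim(arr)
  if (is.null(d)) stop("'", path, "' does not contain gridded data")
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      arr <- array(arr, dim = d[1:3])
    } else {
      stop("'", path, "' is ", length(d), "D with non-trivial extra axes; ",
           "expected a 3D volume")
    }
  } else if (length(d) < 3L) {
    stop("'", path, "' is ", length(d), "D; expected a 3D volume")
  }
  array(as.vector(arr), dim = dim(arr))   # drop NIfTI header attributes
}

#' Read a study from a manifest CSV
#'
#' The manifest maps files to their role, one row per file, with columns
#' `file`, `kind` (`"volume"` or `"mask"`), `subject_id`, `sequence_id`,
#' `structure_label` (masks only) and `observer_id` (masks only). Relative
#' paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `phantom_study`-shaped list: `volumes[[subject]][[sequence]]`,
#'   `observer_masks[[subject]][[sequence]][[structure]][[observer]]`, plus
#'   reference masks under their own structure labels (`fat`, `noise`).
#' @export
read_study_manifest <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "kind", "subject_id", "sequence_id")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(f) ifelse(grepl("^(/|[A-Za-z]:)", f), f,
                                file.path(base, f))
  man$file <- resolve(man$file)
  miss <- !file.exists(man$file)
  if (any(miss))
    stop("manifest references missing files: ",
         paste(man$file[miss], collapse = ", "))

  volumes <- list(); masks <- list()
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    if (r$kind == "volume") {
      v <- load_volume(r$file, r$sequence_id, r$subject_id)
      volumes[[r$subject_id]][[r$sequence_id]] <- v
    } else if (r$kind == "mask") {
      m <- load_mask(r$file, r$structure_label, r$observer_id,
                     r$subject_id, r$sequence_id)
      masks[[length(masks) + 1L]] <- m
    } else stop("unknown manifest kind '", r$kind, "' at row ", i)
  }
  study <- list(volumes = volumes, observer_masks = list())
  for (m in masks) {
    vol <- volumes[[m$subject_id]][[m$sequence_id]]
    if (!is.null(vol)) check_same_grid(m, vol)
    study$observer_masks[[m$subject_id]][[m$sequence_id]][[
      m$structure_label]][[m$observer_id]] <- m
  }
  class(study) <- "phantom_study"
  study
}
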