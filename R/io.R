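#' Write a clip as multi-frame 8-bit grayscale TIFF with JSON sidecar
#'
#' @param clip an `lus_clip`.
#' @param path output TIFF path; metadata (pixel spacing, frame rate,
#'   phase, ground truth when synthetic) is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_clip_tiff <- function(clip, path) {
  frames <- lapply(seq_len(dim(clip$frames)[3]),
                   function(f) clip$frames[, , f] / 255)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  meta <- list(
    pixel_spacing_cm_per_px = clip$pixel_spacing_cm_per_px,
    frame_rate_hz = clip$frame_rate_hz,
    gain = clip$gain,
    pleural_depth_cm = clip$pleural_depth_cm,
    phase = clip$phase,
    true_air_fraction = clip$true_air_fraction,
    true_grade = clip$true_grade
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF clip (with optional JSON sidecar)
#'
#' @param path TIFF path; if `<path>.json` exists its metadata is attached.
#' @param pixel_spacing_cm_per_px used when no sidecar is present.
#' @return an `lus_clip`.
#' @export
read_clip_tiff <- function(path, pixel_spacing_cm_per_px = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames))
    arr[, , f] <- as.integer(round(frames[[f]] * 255))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  sp <- meta$pixel_spacing_cm_per_px %||% pixel_spacing_cm_per_px
  if (is.null(sp))
    stop_domain("pixel spacing unknown: no sidecar and no explicit value")
  structure(list(
    frames = arr,
    pixel_spacing_cm_per_px = sp,
    frame_rate_hz = meta$frame_rate_hz %||% NA_real_,
    gain = meta$gain %||% NA_real_,
    pleural_depth_cm = meta$pleural_depth_cm %||% NA_real_,
    phase = meta$phase %||% NA_character_,
    true_air_fraction = meta$true_air_fraction %||% NA_real_,
    true_grade = meta$true_grade %||% NA_real_
  ), class = "lus_clip")
}

#' Write a CT phantom as NIfTI gray volume plus integer-label mask
#'
#' @param volume a [ct_volume()].
#' @param gray_path,mask_path output NIfTI paths (the mask is 0 background,
#'   1 lung). The probe axis is written to `<gray_path>.json`.
#' @return `gray_path`, invisibly.
#' @export
write_phantom_nifti <- function(volume, gray_path, mask_path) {
  vox <- volume$voxel_size_mm
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- vox
  RNifti::writeNifti(img, gray_path)
  msk <- RNifti::asNifti(array(as.integer(volume$lung_mask),
                               dim(volume$lung_mask)))
  RNifti::pixdim(msk) <- vox
  RNifti::writeNifti(msk, mask_path)
  jsonlite::write_json(list(probe_axis = volume$probe_axis,
                            voxel_size_mm = vox),
                       paste0(gray_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(gray_path)
}

#' Read a CT volume from NIfTI gray + mask files
#'
#' @param gray_path,mask_path NIfTI paths as written by
#'   [write_phantom_nifti()].
#' @param probe_axis override for the probe axis (otherwise taken from the
#'   JSON sidecar, defaulting to 1).
#' @return a [ct_volume()].
#' @export
read_phantom_nifti <- function(gray_path, mask_path, probe_axis = NULL) {
  gray <- RNifti::readNifti(gray_path)
  mask <- RNifti::readNifti(mask_path)
  meta_path <- paste0(gray_path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  vox <- RNifti::pixdim(gray)[1:3]
  ct_volume(array(as.numeric(gray), dim(gray)[1:3]), vox,
            array(as.numeric(mask) != 0, dim(mask)[1:3]),
            probe_axis = probe_axis %||% meta$probe_axis %||% 1L)
}

#' Read ROI annotations from JSON
#'
#' Expects records of the form
#' `{"clip_id": ..., "rois": [{"top_row":..,"left_col":..,"depth_cm":..,"width_px":..}, ...]}`.
#'
#' @param path JSON file path.
#' @return named list (by clip id) of lists of [roi_spec()] objects.
#' @export
read_roi_json <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- list()
  for (rec in recs) {
    out[[rec$clip_id]] <- lapply(rec$rois, function(r)
      roi_spec(r$top_row, r$left_col, r$depth_cm, r$width_px))
  }
  out
}
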