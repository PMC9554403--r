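#' Construct a CT volume with lung mask
#'
#' Container for a reconstructed gray-value volume (attenuation, m^-1) with
#' a binary lung mask. The probe-facing pleural surface is taken to be the
#' lung-mask boundary facing the low end of `probe_axis` (the transducer
#' side); superficial-region depths are measured from that surface.
#'
#' @param voxels 3-D numeric array of gray values.
#' @param voxel_size_mm per-axis voxel edge lengths in mm (length 3).
#' @param lung_mask 3-D logical array of the same dimensions.
#' @param probe_axis array axis (1, 2 or 3) pointing away from the probe;
#'   depth increases with the index along this axis.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, voxel_size_mm, lung_mask, probe_axis = 1L) {
  if (!identical(dim(voxels), dim(lung_mask)))
    stop_domain("voxels and lung_mask must have identical dimensions")
  if (length(dim(voxels)) != 3L)
    stop_domain("voxels must be a 3-D array")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_domain("voxel_size_mm must be three positive lengths")
  if (!probe_axis %in% 1:3)
    stop_domain("probe_axis must be 1, 2 or 3")
  structure(list(voxels = voxels,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 lung_mask = lung_mask == TRUE,
                 probe_axis = as.integer(probe_axis)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (%.2g x %.2g x %.2g mm), %d lung voxels\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], sum(x$lung_mask)))
  invisible(x)
}

#' Segment air voxels by gray-value threshold
#'
#' A voxel counts as air when its gray value is strictly below `threshold`
#' (attenuation scale, default 0.15 m^-1) and it lies inside the lung mask.
#'
#' @param volume a [ct_volume()].
#' @param threshold positive gray-value threshold.
#' @return logical 3-D array, `TRUE` for air voxels within the lung.
#' @export
segment_air <- function(volume, threshold = 0.15) {
  if (!inherits(volume, "ct_volume"))
    stop_domain("volume must be a ct_volume")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_domain("threshold must be a single positive gray value")
  (volume$voxels < threshold) & volume$lung_mask
}

# probe-facing boundary of the lung: lung voxels whose neighbour one step
# toward the probe (lower index along probe_axis) is outside the lung
probe_facing_boundary <- function(lung_mask, probe_axis) {
  d <- dim(lung_mask)
  shifted <- array(FALSE, d)
  # shifted[i] <- lung_mask[i - 1] along probe_axis; first slice -> FALSE
  src <- lung_mask
  if (probe_axis == 1L) {
    shifted[2:d[1], , ] <- src[seq_len(d[1] - 1L), , ]
  } else if (probe_axis == 2L) {
    shifted[, 2:d[2], ] <- src[, seq_len(d[2] - 1L), ]
  } else {
    shifted[, , 2:d[3]] <- src[, , seq_len(d[3] - 1L)]
  }
  lung_mask & !shifted
}

#' Superficial lung region within a depth of the pleural surface
#'
#' Identifies the lung voxels whose Euclidean distance (anisotropic voxel
#' sizes respected) from the probe-facing lung boundary is strictly less
#' than `depth_mm`, so a 10-mm depth on a 1-mm grid selects exactly the ten
#' most superficial voxel layers of a flat surface. The boundary is the set
#' of lung voxels whose neighbour one step toward the probe lies outside
#' the lung; distances are computed with an exact separable Euclidean
#' distance transform.
#'
#' @param volume a [ct_volume()].
#' @param depth_mm region depth from the pleural surface, mm (default 10,
#'   i.e. the superficial 1 cm of lung).
#' @return logical 3-D array marking the superficial region.
#' @export
superficial_region <- function(volume, depth_mm = 10) {
  if (!inherits(volume, "ct_volume"))
    stop_domain("volume must be a ct_volume")
  if (depth_mm <= 0) stop_domain("depth_mm must be positive")
  if (!any(volume$lung_mask)) stop_domain("lung mask is empty")
  boundary <- probe_facing_boundary(volume$lung_mask, volume$probe_axis)
  d2 <- .edt3d_squared(as.vector(boundary), dim(volume$lung_mask),
                       volume$voxel_size_mm)
  dist <- array(sqrt(d2), dim(volume$lung_mask))
  volume$lung_mask & (dist < depth_mm)
}

#' Proportion of air voxels within a region
#'
#' @param air_mask logical 3-D array of air voxels (e.g. [segment_air()]).
#' @param region_mask logical 3-D array of the region of interest
#'   (e.g. [superficial_region()]).
#' @return a list of class `air_proportion_result` with `air_voxels`,
#'   `region_voxels` and `proportion` (= air/region, in `[0,1]`).
#' @export
air_proportion <- function(air_mask, region_mask) {
  if (!identical(dim(air_mask), dim(region_mask)))
    stop_domain("air_mask and region_mask must have identical dimensions")
  region_voxels <- sum(region_mask)
  if (region_voxels == 0L) stop_domain("region mask is empty")
  air_voxels <- sum(air_mask & region_mask)
  structure(list(air_voxels = air_voxels,
                 region_voxels = region_voxels,
                 proportion = air_voxels / region_voxels),
            class = "air_proportion_result")
}

#' Measure the superficial air proportion of a CT volume
#'
#' Convenience composition of [segment_air()], [superficial_region()] and
#' [air_proportion()]: the ground-truth aeration measurement.
#'
#' @inheritParams segment_air
#' @inheritParams superficial_region
#' @return an `air_proportion_result`.
#' @export
measure_ct_aeration <- function(volume, threshold = 0.15, depth_mm = 10) {
  air <- segment_air(volume, threshold)
  region <- superficial_region(volume, depth_mm)
  air_proportion(air, region)
}
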