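#' Region-of-interest specification
#'
#' Rectangular lung-area region below the pleural line and between rib
#' shadows. Coordinates are 0-based pixel indices with row 0 at the
#' transducer face, so depth increases with `top_row`.
#'
#' @param top_row,left_col 0-based pixel coordinates of the top-left corner.
#' @param depth_cm region depth in cm; `depth_cm / pixel_spacing` must give
#'   an integer row count. The standard depths are 2, 3 and 4 cm.
#' @param width_px region width in pixels (>= 8).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(top_row, left_col, depth_cm, width_px) {
  if (width_px < 8) stop_domain("width_px must be >= 8")
  if (top_row < 0 || left_col < 0)
    stop_domain("top_row and left_col must be >= 0")
  if (depth_cm <= 0) stop_domain("depth_cm must be positive")
  structure(list(top_row = as.integer(top_row),
                 left_col = as.integer(left_col),
                 depth_cm = depth_cm,
                 width_px = as.integer(width_px)),
            class = "roi_spec")
}

roi_rows <- function(roi, pixel_spacing_cm_per_px) {
  n <- roi$depth_cm / pixel_spacing_cm_per_px
  if (abs(n - round(n)) > 1e-8)
    stop_domain("depth_cm must be an integer number of pixel rows at this spacing")
  as.integer(round(n))
}

#' Extract a rectangular ROI from a frame
#'
#' @param frame 2-D pixel matrix (rows = depth).
#' @param roi a [roi_spec()].
#' @param pixel_spacing_cm_per_px physical pixel size used to convert
#'   `depth_cm` into rows.
#' @return the pixel block (`depth_cm/spacing` rows by `width_px` columns),
#'   values untouched.
#' @export
#' @examples
#' f <- matrix(1:100, 10, 10)
#' extract_roi(f, roi_spec(0, 0, depth_cm = 1, width_px = 10), 0.1)
extract_roi <- function(frame, roi, pixel_spacing_cm_per_px) {
  nr <- roi_rows(roi, pixel_spacing_cm_per_px)
  r0 <- roi$top_row + 1L       # 0-based spec coordinates -> 1-based indexing
  c0 <- roi$left_col + 1L
  if (r0 + nr - 1L > nrow(frame) || c0 + roi$width_px - 1L > ncol(frame))
    stop_domain("ROI exceeds frame bounds")
  frame[r0:(r0 + nr - 1L), c0:(c0 + roi$width_px - 1L), drop = FALSE]
}

#' Mean pixel intensity of a block
#'
#' @param block non-empty numeric pixel matrix.
#' @return arithmetic mean of all pixels.
#' @export
mean_pixel_intensity <- function(block) {
  if (length(block) == 0L) stop_domain("block is empty")
  mean(block)
}

#' Coefficient of variation of pixel intensity
#'
#' Population standard deviation divided by the mean.
#'
#' @param block non-empty numeric pixel matrix with positive mean.
#' @return unitless CoV (>= 0).
#' @export
coefficient_of_variation <- function(block) {
  if (length(block) == 0L) stop_domain("block is empty")
  m <- mean(block)
  if (m <= 0)
    stop_domain("coefficient of variation undefined for non-positive mean")
  n <- length(block)
  sd_pop <- sqrt(sum((block - m)^2) / n)
  sd_pop / m
}

#' Band-integrated directional Fourier power of a block
#'
#' Computes 1-D discrete Fourier power spectra along the stated axis --
#' `"parallel"` transforms across columns (along the pleural-line
#' direction, sensitive to vertical B-line streaks), `"perpendicular"`
#' transforms along rows (with depth, sensitive to horizontal A-line
#' bands) -- averages the per-line spectra over the orthogonal axis, and
#' integrates the averaged spectrum over the requested spatial-frequency
#' band by the trapezoid rule.
#'
#' Per line of length `N`, the power at frequency index `k` is
#' `|X_k|^2 / N^2` with `X_k` the unnormalised DFT coefficient, and the
#' physical frequency is `k / (N * spacing)` cycles/cm. The band must
#' exclude the zero frequency, so the statistic is invariant to constant
#' offsets; under intensity scaling by `a` it scales as `a^2`.
#'
#' @param block numeric pixel matrix, at least 16 px long in the
#'   transformed direction.
#' @param axis `"parallel"` or `"perpendicular"` to the pleural line.
#' @param band_cycles_per_cm frequency interval `c(lo, hi)` in cycles/cm,
#'   with `lo > 0` (default 0.1--2.0).
#' @param pixel_spacing_cm_per_px physical pixel size.
#' @param hann apply a Hann window per line before transforming
#'   (default `FALSE`).
#' @return integrated band power (>= 0).
#' @export
power_spectrum_auc <- function(block, axis = c("parallel", "perpendicular"),
                               band_cycles_per_cm = c(0.1, 2.0),
                               pixel_spacing_cm_per_px,
                               hann = FALSE) {
  axis <- match.arg(axis)
  if (length(band_cycles_per_cm) != 2L ||
      band_cycles_per_cm[1] <= 0 ||
      band_cycles_per_cm[2] <= band_cycles_per_cm[1])
    stop_domain("band must be c(lo, hi) with 0 < lo < hi (DC excluded)")
  # lines run along the transformed direction
  m <- if (axis == "parallel") t(block) else block
  N <- nrow(m)
  if (N < 16L) stop_domain("block must be at least 16 px in the transformed direction")
  if (hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(N) / (N + 1))
    m <- m * w
  }
  nyquist <- 1 / (2 * pixel_spacing_cm_per_px)
  if (band_cycles_per_cm[2] > nyquist + 1e-12)
    stop_domain("band exceeds the Nyquist frequency for this pixel spacing")
  spec <- Mod(stats::mvfft(m))^2 / N^2          # per-line power spectra
  avg <- rowMeans(spec)                          # average over orthogonal axis
  k <- 0:(N %/% 2)
  freq <- k / (N * pixel_spacing_cm_per_px)
  keep <- freq >= band_cycles_per_cm[1] & freq <= band_cycles_per_cm[2]
  if (!any(keep)) return(0)
  trapz_integral(freq[keep], avg[k[keep] + 1L])
}

#' Feature-extraction settings
#'
#' Depth assignments and Fourier band used when pooling per-clip features:
#' mean pixel intensity and both spectral areas are computed on 4-cm ROIs,
#' the coefficient of variation on 2-cm ROIs.
#'
#' @param band_cycles_per_cm spatial-frequency band in cycles/cm.
#' @param mpi_depth_cm,cov_depth_cm,auc_depth_cm ROI depth (cm) feeding each
#'   statistic.
#' @param hann apply a Hann window before the Fourier transforms.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(band_cycles_per_cm = c(0.1, 2.0),
                           mpi_depth_cm = 4, cov_depth_cm = 2,
                           auc_depth_cm = 4, hann = FALSE) {
  structure(list(band_cycles_per_cm = band_cycles_per_cm,
                 mpi_depth_cm = mpi_depth_cm, cov_depth_cm = cov_depth_cm,
                 auc_depth_cm = auc_depth_cm, hann = hann),
            class = "feature_config")
}

select_rois <- function(rois, depth_cm, statistic) {
  depths <- vapply(rois, function(r) r$depth_cm, numeric(1))
  sel <- rois[abs(depths - depth_cm) < 1e-9]
  if (length(sel) == 0L) {
    if (length(unique(depths)) == 1L) return(rois)   # single-depth fallback
    stop_domain(sprintf("no ROI of depth %g cm available for %s",
                        depth_cm, statistic))
  }
  sel
}

# per-ROI statistic: mean over frames within the ROI, then area-weighted
# mean across ROIs
pool_stat <- function(clip, rois, stat_fn) {
  nF <- dim(clip$frames)[3]
  vals <- numeric(length(rois))
  areas <- numeric(length(rois))
  for (j in seq_along(rois)) {
    roi <- rois[[j]]
    per_frame <- numeric(nF)
    for (f in seq_len(nF)) {
      block <- extract_roi(clip$frames[, , f], roi,
                           clip$pixel_spacing_cm_per_px)
      per_frame[f] <- stat_fn(block)
    }
    vals[j] <- mean(per_frame)
    areas[j] <- roi_rows(roi, clip$pixel_spacing_cm_per_px) * roi$width_px
  }
  sum(vals * areas) / sum(areas)
}

#' Pooled per-clip feature vector
#'
#' For each statistic, per-ROI per-frame values are averaged over frames
#' within each ROI and then combined across ROIs by an area-weighted mean.
#' Mean pixel intensity and the two spectral areas use the 4-cm ROIs, the
#' coefficient of variation the 2-cm ROIs (configurable via
#' [feature_config()]); if all supplied ROIs share a single depth it is
#' used for every statistic.
#'
#' @param clip an `lus_clip` (see [generate_clip()] or [read_clip_tiff()]).
#' @param rois list of [roi_spec()] objects (at least one).
#' @param config a [feature_config()].
#' @return a one-row data frame: `mpi`, `cov`, `auc_parallel`,
#'   `auc_perpendicular`, `n_frames`, `roi_area_px` (total area of all
#'   supplied ROIs).
#' @export
clip_features <- function(clip, rois, config = feature_config()) {
  if (length(rois) == 0L) stop_domain("at least one ROI is required")
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  sp <- clip$pixel_spacing_cm_per_px
  mpi_rois <- select_rois(rois, config$mpi_depth_cm, "MPI")
  cov_rois <- select_rois(rois, config$cov_depth_cm, "CoV")
  auc_rois <- select_rois(rois, config$auc_depth_cm, "spectral AUC")
  mpi <- pool_stat(clip, mpi_rois, mean_pixel_intensity)
  cv <- pool_stat(clip, cov_rois, coefficient_of_variation)
  auc_par <- pool_stat(clip, auc_rois, function(b)
    power_spectrum_auc(b, "parallel", config$band_cycles_per_cm, sp,
                       config$hann))
  auc_perp <- pool_stat(clip, auc_rois, function(b)
    power_spectrum_auc(b, "perpendicular", config$band_cycles_per_cm, sp,
                       config$hann))
  data.frame(
    mpi = mpi, cov = cv, auc_parallel = auc_par,
    auc_perpendicular = auc_perp,
    n_frames = dim(clip$frames)[3],
    roi_area_px = sum(vapply(rois, function(r)
      roi_rows(r, sp) * r$width_px, numeric(1)))
  )
}

#' Default ROIs for synthetic clips
#'
#' Places ROIs just below the pleural line, centred between the two rib
#' shadows, at every requested depth that fits inside the frame.
#'
#' @param config a [simulation_config()].
#' @param depths_cm candidate ROI depths in cm (default 2, 3 and 4).
#' @return list of [roi_spec()] objects.
#' @export
default_rois <- function(config, depths_cm = c(2, 3, 4)) {
  s <- config$pixel_spacing_cm_per_px
  pr0 <- round(config$pleural_depth_cm / s)       # 0-based pleural row
  top <- pr0 + 3L
  cols <- inner_cols(config$image_width_px)
  left <- min(cols) - 1L                          # 0-based
  width <- length(cols)
  out <- list()
  for (d in depths_cm) {
    nr <- round(d / s)
    if (top + nr <= config$image_height_px)
      out[[length(out) + 1L]] <- roi_spec(top, left, d, width)
  }
  if (length(out) == 0L)
    stop_domain("no requested ROI depth fits inside the frame")
  out
}
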