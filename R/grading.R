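#' Validate an ordinal LUS grade
#'
#' The grading scale describes the sonographic appearance of the aerating
#' lung: 0 (hepatization, liquid-filled), 0.5 (speckled pleural line),
#' 1 (white-out), 2 (mixed A- and B-lines), 3 (A-lines only).
#'
#' @param value numeric grade, one of 0, 0.5, 1, 2, 3.
#' @return the validated grade.
#' @export
grade_label <- function(value) {
  if (length(value) != 1L || !value %in% c(0, 0.5, 1, 2, 3))
    stop_domain("grade must be one of 0, 0.5, 1, 2, 3")
  value
}

#' Two-rater consensus grade with tiebreaker
#'
#' If the two blinded raters agree, their grade is the consensus; on
#' disagreement the third rater's grade is used as the tiebreaker.
#'
#' @param rater1,rater2 grades from the two primary raters.
#' @param rater3 optional tiebreaker grade; required when the primary
#'   raters disagree.
#' @return the consensus grade.
#' @export
#' @examples
#' consensus_grade(1, 1)        # agreement
#' consensus_grade(1, 2, 2)     # tiebreak
consensus_grade <- function(rater1, rater2, rater3 = NULL) {
  r1 <- grade_label(rater1); r2 <- grade_label(rater2)
  if (r1 == r2) return(r1)
  if (is.null(rater3))
    stop_domain("raters disagree and no tiebreaker grade was provided")
  grade_label(rater3)
}

# depth profile of a clip: mean over frames, then mean over the columns
# between the rib shadows
clip_depth_profile <- function(clip) {
  mean_frame <- apply(clip$frames, c(1, 2), mean)
  cols <- inner_cols(ncol(mean_frame))
  list(mean_frame = mean_frame,
       inner = cols,
       profile = rowMeans(mean_frame[, cols, drop = FALSE]))
}

#' Rule-based automatic grade for synthetic clips
#'
#' A deterministic cascade over image-derived pleural and artifact metrics,
#' intended as a surrogate rater for generator output (a synthetic-data
#' convenience calibrated on the generator's morphology, not a clinical
#' classifier): absent pleural echo maps to 0; a fragmented, multi-depth
#' pleural echo to 0.5; a bright confluent field with low column-to-column
#' variation to 1; B-line streaks together with A-line reverberation peaks
#' to 2; A-line peaks without a subpleural field to 3.
#'
#' @param clip an `lus_clip`.
#' @param pleural_depth_cm expected transducer-to-pleura distance (defaults
#'   to the clip's own metadata).
#' @return a grade from `{0, 0.5, 1, 2, 3}`.
#' @export
auto_grade <- function(clip, pleural_depth_cm = clip$pleural_depth_cm) {
  s <- clip$pixel_spacing_cm_per_px
  dp <- clip_depth_profile(clip)
  prof <- dp$profile
  H <- length(prof)
  pr <- round(pleural_depth_cm / s)

  # tissue background from the rows above the pleura (always artifact-free)
  bg <- stats::median(prof[seq_len(max(2L, pr - 4L))])

  if (max(prof) < bg + 25) return(0)            # no echo anywhere

  # continuity of the pleural echo: fraction of columns with a bright pixel
  # within +/- 3 px of the nominal pleural depth (frame-averaged)
  band <- clamp((pr - 3L):(pr + 4L), 1L, H)
  col_max <- apply(dp$mean_frame[band, dp$inner, drop = FALSE], 2, max)
  coverage <- mean(col_max > bg + 80)
  if (coverage < 0.6) return(0.5)               # fragmented, multi-depth echo

  # subpleural field: band 0.3-2 cm below the pleural line
  f0 <- clamp(pr + round(0.3 / s), 1L, H)
  f1 <- clamp(pr + round(2.0 / s), 1L, H)
  field <- dp$mean_frame[f0:f1, dp$inner, drop = FALSE]
  field_mean <- mean(field)
  colprof <- colMeans(field)
  col_cv <- stats::sd(colprof) / mean(colprof)

  # A-line reverberation peak near twice the pleural depth vs. its flanks
  a_band <- clamp((2L * pr - 3L):(2L * pr + 4L), 1L, H)
  flank <- clamp(c((2L * pr - 14L):(2L * pr - 7L),
                   (2L * pr + 8L):(2L * pr + 15L)), 1L, H)
  has_aline <- max(prof[a_band]) > stats::median(prof[flank]) + 12

  if (field_mean < 70) {
    # bright pleura but next to no subpleural field
    return(if (has_aline) 3 else 0.5)
  }
  if (col_cv < 0.30) 1 else 2
}

#' Median (IQR) air proportion per LUS grade
#'
#' Summarises observations the way the grading scale is reported: the
#' median and interquartile range of the CT-measured air proportion within
#' each grade, in percent. Grades with no observations are reported with
#' `NA` entries.
#'
#' @param grades numeric vector of grades (values in 0, 0.5, 1, 2, 3).
#' @param air_proportions air proportions in `[0,1]`, same length.
#' @return data frame with columns `grade`, `n`, `median_air_pct`,
#'   `iqr_low_pct`, `iqr_high_pct`.
#' @export
grade_vs_air_summary <- function(grades, air_proportions) {
  if (length(grades) == 0L) stop_domain("no observations supplied")
  if (length(grades) != length(air_proportions))
    stop_domain("grades and air_proportions must have equal length")
  levels <- c(0, 0.5, 1, 2, 3)
  out <- lapply(levels, function(g) {
    v <- air_proportions[grades == g] * 100
    if (length(v) == 0L)
      return(data.frame(grade = g, n = 0L, median_air_pct = NA_real_,
                        iqr_low_pct = NA_real_, iqr_high_pct = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(grade = g, n = length(v), median_air_pct = q[2],
               iqr_low_pct = q[1], iqr_high_pct = q[3])
  })
  do.call(rbind, out)
}
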