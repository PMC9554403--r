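#' Simulation configuration for paired LUS clips and CT phantoms
#'
#' Bundles the geometry, artifact and noise parameters of the synthetic-data
#' generator. The defaults emulate the acquisition conditions the analysis
#' assumes: 3-s cine clips at 15 frames/s (45 frames), a linear-array B-mode
#' geometry with the pleural line at a fixed depth, and phase-contrast CT
#' gray values on the attenuation scale (per metre) with air segmented below
#' a fixed threshold.
#'
#' @param image_height_px,image_width_px frame dimensions in pixels; depth
#'   increases with row index (row 0 at the transducer face).
#' @param pixel_spacing_cm_per_px physical pixel size, cm per pixel
#'   (default 0.01, so a 4-cm region of interest is 400 px deep).
#' @param frames_per_clip frames per cine clip (default 45 = 3 s at 15 Hz).
#' @param frame_rate_hz nominal frame rate, Hz.
#' @param pleural_depth_cm transducer-to-pleura distance, cm. A-line
#'   reverberation bands appear at integer multiples of this depth.
#' @param aline_decay geometric intensity decay ratio of successive A-line
#'   reverberations, in (0,1).
#' @param bline_count_max maximum number of distinct B-line streaks drawn at
#'   the low-aeration end of the type-1/2 range.
#' @param speckle_sigma log-scale dispersion of the multiplicative
#'   (log-normal) speckle applied per pixel per frame.
#' @param gain_sigma log-scale dispersion of the per-clip multiplicative
#'   gain jitter (clip-level brightness noise that does not average out
#'   across frames).
#' @param morph_sigma standard deviation of the per-clip jitter applied to
#'   the aeration-to-morphology mapping; the dominant clip-level noise
#'   source for all four image statistics.
#' @param deflation_noise_multiplier factor (>= 1) applied to
#'   `speckle_sigma`, `gain_sigma` and `morph_sigma` when the clip is
#'   acquired during deflation, encoding the weaker image-to-aeration
#'   coupling observed on the deflation limb.
#' @param grade_thresholds four strictly increasing air-fraction breakpoints
#'   in (0,1) (the first may be 0) separating grades 0 / 0.5 / 1 / 2 / 3.
#' @param air_gray_value,tissue_gray_value CT gray levels (attenuation,
#'   m^-1) around which air and tissue/liquid voxels are drawn.
#' @param air_threshold CT gray level below which a voxel counts as air
#'   (default 0.15 m^-1).
#' @param ct_grid_dim CT phantom grid size per axis (cubic grid).
#' @param ct_voxel_size_mm CT voxel size per axis, mm (length 3).
#' @param seed default integer seed recorded with the configuration.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(image_height_px = 160, image_width_px = 64,
#'                          pixel_spacing_cm_per_px = 0.04)
#' clip <- generate_clip(cfg, air_fraction = 0.6, seed = 1)
#' clip$true_grade
simulation_config <- function(image_height_px = 480L,
                              image_width_px = 384L,
                              pixel_spacing_cm_per_px = 0.01,
                              frames_per_clip = 45L,
                              frame_rate_hz = 15,
                              pleural_depth_cm = 0.6,
                              aline_decay = 0.55,
                              bline_count_max = 8L,
                              speckle_sigma = 0.25,
                              gain_sigma = 0.10,
                              morph_sigma = 0.06,
                              deflation_noise_multiplier = 1.5,
                              grade_thresholds = c(0, 0.15, 0.50, 0.85),
                              air_gray_value = 0.05,
                              tissue_gray_value = 0.40,
                              air_threshold = 0.15,
                              ct_grid_dim = 64L,
                              ct_voxel_size_mm = c(0.5, 0.5, 0.5),
                              seed = 1L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_spacing_cm_per_px = pixel_spacing_cm_per_px,
    frames_per_clip = as.integer(frames_per_clip),
    frame_rate_hz = frame_rate_hz,
    pleural_depth_cm = pleural_depth_cm,
    aline_decay = aline_decay,
    bline_count_max = as.integer(bline_count_max),
    speckle_sigma = speckle_sigma,
    gain_sigma = gain_sigma,
    morph_sigma = morph_sigma,
    deflation_noise_multiplier = deflation_noise_multiplier,
    grade_thresholds = as.numeric(grade_thresholds),
    air_gray_value = air_gray_value,
    tissue_gray_value = tissue_gray_value,
    air_threshold = air_threshold,
    ct_grid_dim = as.integer(ct_grid_dim),
    ct_voxel_size_mm = as.numeric(ct_voxel_size_mm),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

#' Desk-scale simulation configuration
#'
#' Identical physics to [simulation_config()] but sampled on a 0.02 cm/px
#' grid (240 x 192 px), halving each linear image dimension. The field of
#' view, ROI extents in cm, artifact morphology, noise model and pressure
#' response are unchanged; only the pixel grid is coarser, which keeps
#' cohort-scale simulations fast.
#'
#' @param ... overrides passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @export
desk_simulation_config <- function(...) {
  simulation_config(image_height_px = 240L, image_width_px = 192L,
                    pixel_spacing_cm_per_px = 0.02, ...)
}

validate_simulation_config <- function(cfg) {
  if (cfg$image_height_px < 16L || cfg$image_width_px < 16L)
    stop_domain("image dimensions must be at least 16 px")
  if (cfg$frames_per_clip < 1L)
    stop_domain("frames_per_clip must be >= 1")
  if (cfg$pixel_spacing_cm_per_px <= 0)
    stop_domain("pixel_spacing_cm_per_px must be positive")
  if (cfg$aline_decay <= 0 || cfg$aline_decay >= 1)
    stop_domain("aline_decay must lie in (0,1)")
  if (cfg$speckle_sigma < 0)
    stop_domain("speckle_sigma must be >= 0")
  if (cfg$deflation_noise_multiplier < 1)
    stop_domain("deflation_noise_multiplier must be >= 1")
  gt <- cfg$grade_thresholds
  if (length(gt) != 4L || any(diff(gt) <= 0) || any(gt < 0) || any(gt >= 1))
    stop_domain("grade_thresholds must be four strictly increasing values in [0,1)")
  if (!(cfg$air_gray_value < cfg$air_threshold &&
        cfg$air_threshold < cfg$tissue_gray_value))
    stop_domain("need air_gray_value < air_threshold < tissue_gray_value")
  if (length(cfg$ct_voxel_size_mm) != 3L || any(cfg$ct_voxel_size_mm <= 0))
    stop_domain("ct_voxel_size_mm must be three positive lengths")
  invisible(cfg)
}

#' Map an air fraction to its ordinal LUS grade
#'
#' Grades are the bins of the air fraction under the configured breakpoints
#' `(t1, t2, t3, t4)`: grade 0 for `af <= t1`, 0.5 for `t1 < af < t2`,
#' 1 for `t2 <= af < t3`, 2 for `t3 <= af < t4` and 3 for `af >= t4`.
#'
#' @param air_fraction proportion(s) of air in `[0,1]`.
#' @param thresholds four increasing breakpoints (see [simulation_config()]).
#' @return numeric grade(s) from `{0, 0.5, 1, 2, 3}`.
#' @export
grade_from_air_fraction <- function(air_fraction,
                                    thresholds = c(0, 0.15, 0.50, 0.85)) {
  if (any(air_fraction < 0 | air_fraction > 1))
    stop_domain("air_fraction must lie in [0,1]")
  t <- thresholds
  g <- ifelse(air_fraction <= t[1], 0,
       ifelse(air_fraction < t[2], 0.5,
       ifelse(air_fraction < t[3], 1,
       ifelse(air_fraction < t[4], 2, 3))))
  g
}

#' Pressure schedule for a simulated inflation/deflation sequence
#'
#' @param pressures_cmH2O airway pressures in cmH2O, each in `[0, 50]`.
#' @param phases character vector of the same length with values
#'   `"inflation"`, `"deflation"` or `"suction"`. Inflation pressures must
#'   be non-decreasing, deflation pressures non-increasing, and suction may
#'   only occur at the end.
#' @return a `pressure_schedule` data frame with columns `pressure_cmH2O`
#'   and `phase`.
#' @export
#' @examples
#' default_pressure_schedule()
pressure_schedule <- function(pressures_cmH2O, phases) {
  if (length(pressures_cmH2O) == 0L)
    stop_domain("schedule must contain at least one step")
  if (length(pressures_cmH2O) != length(phases))
    stop_domain("pressures and phases must have equal length")
  phases <- match.arg(phases, c("inflation", "deflation", "suction"),
                      several.ok = TRUE)
  if (any(pressures_cmH2O < 0 | pressures_cmH2O > 50))
    stop_domain("pressures must lie in [0, 50] cmH2O")
  infl <- pressures_cmH2O[phases == "inflation"]
  defl <- pressures_cmH2O[phases == "deflation"]
  if (length(infl) > 1L && any(diff(infl) < 0))
    stop_domain("inflation pressures must be non-decreasing")
  if (length(defl) > 1L && any(diff(defl) > 0))
    stop_domain("deflation pressures must be non-increasing")
  suct <- which(phases == "suction")
  if (length(suct) && any(suct != seq(length(phases) - length(suct) + 1L,
                                      length(phases))))
    stop_domain("suction steps may only appear at the end of the schedule")
  structure(data.frame(pressure_cmH2O = pressures_cmH2O, phase = phases,
                       stringsAsFactors = FALSE),
            class = c("pressure_schedule", "data.frame"))
}

#' Default pressure schedule
#'
#' Stepwise static inflation from 0 cmH2O, then 15 cmH2O and increments of
#' 5 cmH2O up to 50 cmH2O; deflation back down in 10-cmH2O decrements; a
#' final suction step.
#'
#' @return a `pressure_schedule`.
#' @export
default_pressure_schedule <- function() {
  pressure_schedule(
    c(0, 15, 20, 25, 30, 35, 40, 45, 50, 40, 30, 20, 10, 0, 0),
    c(rep("inflation", 9), rep("deflation", 5), "suction")
  )
}

# rib shadow column ranges (1-based), two dark vertical bands near the
# lateral edges of the field of view
rib_shadow_cols <- function(width_px) {
  b1 <- seq(max(1L, round(0.03 * width_px)), round(0.10 * width_px))
  b2 <- seq(round(0.90 * width_px), min(width_px, round(0.97 * width_px)))
  list(left = b1, right = b2)
}

# columns between the rib shadows, with a small safety margin
inner_cols <- function(width_px) {
  sh <- rib_shadow_cols(width_px)
  seq(max(sh$left) + 3L, min(sh$right) - 3L)
}

# Deterministic noise-free artifact image for one clip (RNG already seeded
# by the caller). Encodes the grade-dependent morphology:
#   0   - dim homogeneous tissue, no pleural echo
#   0.5 - discontinuous bright pleural segments at varying depths
#   1   - bright confluent field below the pleura ("white-out")
#   2   - distinct vertical B-line streaks + horizontal A-line bands at
#         integer multiples of the pleural depth, geometrically decaying
#   3   - pleural line and A-line bands only
# Within types 1-2 the morphology varies continuously with the air
# fraction: the field dims, the B-line streaks separate and sharpen, and
# A-line bands ramp in, so all four image statistics are monotone readouts
# of aeration over the type-1/2 range.
build_structure <- function(cfg, air_fraction, phase_mult) {
  H <- cfg$image_height_px; W <- cfg$image_width_px
  s <- cfg$pixel_spacing_cm_per_px
  pr <- round(cfg$pleural_depth_cm / s)          # pleural row (0-based depth)
  tissue <- 30
  pleural_intensity <- 230
  grade <- grade_from_air_fraction(air_fraction, cfg$grade_thresholds)
  S <- matrix(tissue, H, W)
  inner <- inner_cols(W)

  if (grade == 0.5) {
    nseg <- 8L
    segw <- max(4L, round(W / 6))
    for (i in seq_len(nseg)) {
      d_cm <- stats::runif(1, cfg$pleural_depth_cm, cfg$pleural_depth_cm + 1.5)
      r0 <- round(d_cm / s)
      c0 <- sample(inner[inner <= max(inner) - segw], 1L)
      rows <- clamp(r0:(r0 + 3L), 1L, H)
      cols <- c0:(c0 + segw - 1L)
      S[rows, cols] <- pmax(S[rows, cols], 200)
    }
  } else if (grade %in% c(1, 2)) {
    t2 <- cfg$grade_thresholds[2]; t4 <- cfg$grade_thresholds[4]
    t_raw <- (air_fraction - t2) / (t4 - t2)
    t <- clamp(t_raw + stats::rnorm(1, 0, cfg$morph_sigma * phase_mult), 0, 1)
    m <- 200 * (1 - 0.55 * t)                    # field level: dims as air rises
    A <- 15 + 160 * t                            # streak contrast: grows
    nb <- max(2L, round(cfg$bline_count_max * (1 - 0.7 * t)))
    smask <- numeric(W)
    centers <- sample(inner, nb)
    for (ctr in centers) {
      w <- sample(4:8, 1L)
      cols <- clamp((ctr - w %/% 2):(ctr + w %/% 2), 1L, W)
      smask[cols] <- 1
    }
    colprof <- m + A * (smask - mean(smask[inner]))
    field_rows <- (pr + 2L):H
    S[field_rows, ] <- matrix(pmax(tissue, colprof), length(field_rows), W,
                              byrow = TRUE)
    S[pr:(pr + 1L), ] <- pleural_intensity
    a_ramp <- clamp((t - 0.45) / 0.55, 0, 1)     # A-lines ramp in over type 2
    S <- add_aline_bands(S, pr, pleural_intensity * a_ramp, cfg$aline_decay)
  } else if (grade == 3) {
    S[pr:(pr + 1L), ] <- pleural_intensity
    S <- add_aline_bands(S, pr, pleural_intensity, cfg$aline_decay)
  }

  sh <- rib_shadow_cols(W)
  S[, c(sh$left, sh$right)] <- S[, c(sh$left, sh$right)] * 0.12
  S
}

# horizontal reverberation bands at depths k * pleural_depth, k >= 2, with
# intensity I0 * decay^(k-1); I0 is the pleural-line intensity
add_aline_bands <- function(S, pleural_row, I0, decay) {
  if (I0 <= 0) return(S)
  H <- nrow(S)
  k <- 2L
  repeat {
    r <- k * pleural_row
    if (r + 1L > H) break
    val <- I0 * decay^(k - 1L)
    if (val < 1) break
    S[r:(r + 1L), ] <- pmax(S[r:(r + 1L), ], val)
    k <- k + 1L
  }
  S
}

#' Generate one synthetic lung-ultrasound cine clip
#'
#' Renders a grade-dependent artifact image (see [simulation_config()] for
#' the morphology model) and applies multiplicative log-normal speckle per
#' pixel per frame plus a per-clip gain jitter. During deflation all noise
#' dispersions are multiplied by `deflation_noise_multiplier`. Identical
#' arguments and seed reproduce bit-identical frames.
#'
#' @param config a [simulation_config()].
#' @param air_fraction true proportion of air in the superficial lung,
#'   in `[0,1]`; determines the clip's grade and morphology.
#' @param phase `"inflation"`, `"deflation"` or `"suction"` (suction clips
#'   are rendered like inflation clips at their low air fraction).
#' @param seed integer seed for this clip.
#' @return an object of class `lus_clip`: a list with `frames` (an
#'   `height x width x n_frames` integer array, values 0-255),
#'   `pixel_spacing_cm_per_px`, `frame_rate_hz`, `pleural_depth_cm`,
#'   `phase`, `true_air_fraction` and `true_grade`.
#' @export
generate_clip <- function(config, air_fraction, phase = "inflation",
                          seed = config$seed) {
  if (!is.numeric(air_fraction) || length(air_fraction) != 1L ||
      is.na(air_fraction) || air_fraction < 0 || air_fraction > 1)
    stop_domain("air_fraction must be a single value in [0,1]")
  phase <- match.arg(phase, c("inflation", "deflation", "suction"))
  mult <- if (phase == "deflation") config$deflation_noise_multiplier else 1
  H <- config$image_height_px; W <- config$image_width_px
  nF <- config$frames_per_clip
  frames <- with_seed(seed, {
    S <- build_structure(config, air_fraction, mult)
    sigma <- config$speckle_sigma * mult
    gain <- stats::rlnorm(1, 0, config$gain_sigma * mult)
    spk <- stats::rlnorm(H * W * nF, -sigma^2 / 2, sigma)
    f <- array(as.vector(S), c(H, W, nF)) * array(spk, c(H, W, nF)) * gain
    array(as.integer(round(clamp(f, 0, 255))), c(H, W, nF))
  })
  structure(list(
    frames = frames,
    pixel_spacing_cm_per_px = config$pixel_spacing_cm_per_px,
    frame_rate_hz = config$frame_rate_hz,
    gain = 74,
    pleural_depth_cm = config$pleural_depth_cm,
    phase = phase,
    true_air_fraction = air_fraction,
    true_grade = grade_from_air_fraction(air_fraction, config$grade_thresholds)
  ), class = "lus_clip")
}

#' @export
print.lus_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<lus_clip> %d x %d px, %d frames, grade %.1f, air fraction %.3f (%s)\n",
              d[1], d[2], d[3], x$true_grade, x$true_air_fraction, x$phase))
  invisible(x)
}

#' Generate a synthetic CT phantom with known superficial air fraction
#'
#' Builds a gray-value volume plus lung mask in which the probe-facing lung
#' surface sits at a gently curved depth along the first array axis. Within
#' the superficial region (lung voxels within 10 mm of that surface,
#' computed with the same anisotropic Euclidean distance transform the
#' measurement uses) a requested proportion of voxels is assigned air-like
#' gray values; noise amplitudes are bounded so that thresholding at
#' `air_threshold` recovers the assignment without error. A bright
#' tube-like "vessel" structure is placed strictly below the superficial
#' 1-cm region.
#'
#' @param config a [simulation_config()].
#' @param air_fraction requested proportion of air voxels in the superficial
#'   region, in `[0,1]`.
#' @param seed integer seed.
#' @return an object of class `ct_volume` (see [ct_volume()]) with the
#'   extra fields `true_superficial_air_fraction` (the realized proportion)
#'   and `requested_air_fraction`.
#' @export
generate_ct_phantom <- function(config, air_fraction, seed = config$seed) {
  if (!is.numeric(air_fraction) || length(air_fraction) != 1L ||
      is.na(air_fraction) || air_fraction < 0 || air_fraction > 1)
    stop_domain("air_fraction must be a single value in [0,1]")
  n <- config$ct_grid_dim
  vox <- config$ct_voxel_size_mm
  thr <- config$air_threshold
  with_seed(seed, {
    # probe-facing lung surface depth (voxels along axis 1), gently curved
    yy <- seq_len(n); zz <- seq_len(n)
    x0 <- outer(yy, zz, function(y, z)
      4 + round(1.5 * (1 + sin(2 * pi * y / n) * cos(2 * pi * z / n))))
    x1 <- n - 4L
    xs <- slice.index(array(0L, c(n, n, n)), 1L)
    surf <- array(rep(as.vector(x0), each = n), c(n, n, n))  # constant in x
    lung <- xs >= surf & xs <= x1

    vol <- ct_volume(array(0.30, c(n, n, n)), vox, lung)

    region <- superficial_region(vol, depth_mm = 10)
    n_region <- sum(region)
    if (n_region == 0L)
      stop_domain("grid too small: superficial region is empty")
    n_air <- round(air_fraction * n_region)
    realized <- n_air / n_region
    if (abs(realized - air_fraction) > 0.02)
      stop_domain("requested air_fraction unreachable at this grid size")

    air_mask <- array(FALSE, c(n, n, n))
    region_idx <- which(region)
    if (n_air > 0L)
      air_mask[sample(region_idx, n_air)] <- TRUE
    # deep lung aerated at a similar rate (outside the measured region)
    deep_idx <- which(lung & !region)
    n_deep_air <- round(air_fraction * length(deep_idx))
    if (n_deep_air > 0L)
      air_mask[sample(deep_idx, n_deep_air)] <- TRUE

    v <- array(0.30, c(n, n, n))                      # background soft tissue
    tis_idx <- which(lung & !air_mask)
    air_idx <- which(air_mask)
    # bounded noise keeps air strictly below and tissue strictly above thr
    v[tis_idx] <- clamp(stats::rnorm(length(tis_idx), config$tissue_gray_value,
                                     0.05),
                        thr + 0.05, config$tissue_gray_value + 0.2)
    v[air_idx] <- clamp(stats::rnorm(length(air_idx), config$air_gray_value,
                                     0.02),
                        0, thr - 0.02)

    # bright vessel: a tube along axis 3, strictly below the superficial
    # region (centre deeper than max surface depth + 10 mm + margin)
    vx_depth <- max(x0) + ceiling(10 / vox[1]) + 4L
    if (vx_depth + 2L <= x1) {
      cy <- sample(seq(8L, n - 8L), 1L)
      xi <- (vx_depth - 2L):(vx_depth + 2L)
      yi <- clamp((cy - 2L):(cy + 2L), 1L, n)
      dist2 <- outer((xi - vx_depth)^2, (yi - cy)^2, `+`)
      inside <- which(dist2 <= 4, arr.ind = TRUE)
      for (k in seq_len(nrow(inside)))
        v[xi[inside[k, 1]], yi[inside[k, 2]], ] <- config$tissue_gray_value + 0.25
    }

    out <- ct_volume(v, vox, lung)
    out$true_superficial_air_fraction <- realized
    out$requested_air_fraction <- air_fraction
    out
  })
}

# lung-specific saturating pressure-volume parameters
draw_lung_params <- function() {
  list(
    af_max = clamp(stats::rnorm(1, 0.68, 0.05), 0.50, 0.82),
    p50 = clamp(stats::rnorm(1, 26, 2), 20, 32),
    hill = 4,
    hysteresis = clamp(stats::rnorm(1, 0.60, 0.05), 0.45, 0.75)
  )
}

# saturating monotone inflation curve: af = af_max * P^h / (p50^h + P^h)
inflation_air_fraction <- function(pressure, lp) {
  if (pressure <= 0) return(0)
  lp$af_max * pressure^lp$hill / (lp$p50^lp$hill + pressure^lp$hill)
}

#' Generate one paired LUS + CT observation
#'
#' Building block used by [generate_cohort()] and the end-to-end pipeline:
#' renders the clip and the CT phantom for a known air fraction.
#'
#' @param config a [simulation_config()].
#' @param lamb_id,lung_side identifiers.
#' @param pressure_cmH2O airway pressure.
#' @param phase `"inflation"`, `"deflation"` or `"suction"`.
#' @param air_fraction true superficial air fraction.
#' @param seed integer seed for this observation.
#' @param keep_images if `FALSE`, the clip and phantom are generated,
#'   summarised into `clip` = NULL / `ct` = NULL and only metadata kept
#'   (used by callers that stream features).
#' @return a `paired_observation` list.
#' @export
generate_observation <- function(config, lamb_id, lung_side, pressure_cmH2O,
                                 phase, air_fraction, seed,
                                 keep_images = TRUE) {
  clip <- generate_clip(config, air_fraction, phase, seed)
  ct <- generate_ct_phantom(config, air_fraction, derive_seed(seed, 101L))
  obs <- list(
    lamb_id = lamb_id,
    lung_side = lung_side,
    pressure_cmH2O = pressure_cmH2O,
    phase = phase,
    true_air_fraction = air_fraction,
    true_grade = clip$true_grade,
    true_ct_superficial_fraction = ct$true_superficial_air_fraction,
    clip = if (keep_images) clip else NULL,
    ct = if (keep_images) ct else NULL
  )
  class(obs) <- "paired_observation"
  obs
}

#' Generate a cohort of paired LUS/CT observations
#'
#' Each lamb contributes two lungs; each lung is taken through the pressure
#' schedule. Per lung, the air fraction follows a saturating monotone curve
#' of pressure during inflation; at equal pressure the deflation limb holds
#' more air (hysteresis), and deflation clips carry inflated noise. Suction
#' collapses the lung to a small residual air fraction.
#'
#' @param n_lambs number of lambs (>= 1).
#' @param schedule a [pressure_schedule()].
#' @param config a [simulation_config()].
#' @param seed master integer seed.
#' @param keep_images keep the frame stacks and voxel arrays in each
#'   observation (`TRUE`, the default) or only the metadata.
#' @return a list of `paired_observation` objects of length
#'   `n_lambs * 2 * nrow(schedule)`.
#' @export
#' @examples
#' cfg <- simulation_config(image_height_px = 160, image_width_px = 64,
#'                          pixel_spacing_cm_per_px = 0.04,
#'                          frames_per_clip = 3, ct_grid_dim = 24)
#' obs <- generate_cohort(2, default_pressure_schedule(), cfg, seed = 1,
#'                        keep_images = FALSE)
#' length(obs)
generate_cohort <- function(n_lambs, schedule, config = simulation_config(),
                            seed = config$seed, keep_images = TRUE) {
  if (n_lambs < 1L) stop_domain("n_lambs must be >= 1")
  if (!inherits(schedule, "pressure_schedule") || nrow(schedule) == 0L)
    stop_domain("schedule must be a non-empty pressure_schedule")
  plan <- cohort_plan(n_lambs, schedule, seed)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    out[[i]] <- generate_observation(
      config, plan$lamb_id[i], plan$lung_side[i], plan$pressure_cmH2O[i],
      plan$phase[i], plan$true_air_fraction[i], plan$obs_seed[i],
      keep_images = keep_images)
  }
  out
}

# deterministic per-observation plan (lung curves + realized air fractions);
# shared by generate_cohort() and the streaming pipeline
cohort_plan <- function(n_lambs, schedule, seed) {
  rows <- list()
  i <- 0L
  for (lamb in seq_len(n_lambs)) {
    for (side in c("left", "right")) {
      lung_seed <- derive_seed(seed, lamb * 100L + (side == "right"))
      lp <- with_seed(lung_seed, draw_lung_params())
      p_max <- max(schedule$pressure_cmH2O[schedule$phase == "inflation"], 0)
      af_peak <- inflation_air_fraction(p_max, lp)
      infl_realized <- list()   # pressure -> realized inflation air fraction
      for (k in seq_len(nrow(schedule))) {
        i <- i + 1L
        p <- schedule$pressure_cmH2O[k]
        ph <- schedule$phase[k]
        obs_seed <- derive_seed(seed, i * 13L + lamb)
        af <- with_seed(derive_seed(obs_seed, 7L), {
          if (ph == "inflation") {
            if (p <= 0) 0
            else clamp(inflation_air_fraction(p, lp) +
                         stats::rnorm(1, 0, 0.015), 0.001, 1)
          } else if (ph == "deflation") {
            base <- inflation_air_fraction(p, lp)
            floor_af <- max(base, infl_realized[[as.character(p)]] %||% 0)
            candidate <- base + lp$hysteresis * (af_peak - base) +
              stats::rnorm(1, 0, 0.01)
            clamp(max(candidate, floor_af + 1e-6), 0.001, 1)
          } else {
            clamp(stats::rnorm(1, 0.07, 0.02), 0.01, 0.149)
          }
        })
        if (ph == "inflation") infl_realized[[as.character(p)]] <- af
        rows[[i]] <- data.frame(
          lamb_id = sprintf("lamb%02d", lamb), lung_side = side,
          pressure_cmH2O = p, phase = ph, true_air_fraction = af,
          obs_seed = obs_seed, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Metadata table for a cohort
#'
#' @param cohort a list of `paired_observation`s from [generate_cohort()].
#' @return a data frame with one row per observation: identifiers, pressure
#'   (cmH2O), phase, true air fraction, true grade and the phantom's
#'   realized superficial fraction.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(o) data.frame(
    lamb_id = o$lamb_id, lung_side = o$lung_side,
    pressure_cmH2O = o$pressure_cmH2O, phase = o$phase,
    true_air_fraction = o$true_air_fraction, true_grade = o$true_grade,
    true_ct_superficial_fraction = o$true_ct_superficial_fraction,
    stringsAsFactors = FALSE)))
}
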