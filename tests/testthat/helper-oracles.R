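# Independent brute-force oracles, kept deliberately naive: direct loops and
# textbook formulas, no shared code with the implementation paths they check.

# small, fast simulation geometry used throughout the unit tests: same
# physics as the defaults, coarser grid and short clips
tiny_cfg <- function(...) {
  simulation_config(image_height_px = 128L, image_width_px = 64L,
                    pixel_spacing_cm_per_px = 0.04, frames_per_clip = 5L,
                    ct_grid_dim = 24L, ...)
}

oracle_mean <- function(block) {
  s <- 0
  for (v in as.vector(block)) s <- s + v
  s / length(block)
}

oracle_cov <- function(block) {
  m <- oracle_mean(block)
  ss <- 0
  for (v in as.vector(block)) ss <- ss + (v - m)^2
  sqrt(ss / length(block)) / m
}

# naive DFT band power: per line |X_k|^2 / N^2, averaged over lines,
# trapezoid-integrated over frequencies inside the band
oracle_power_auc <- function(block, axis, band, spacing) {
  lines <- if (axis == "parallel") {
    lapply(seq_len(nrow(block)), function(r) block[r, ])
  } else {
    lapply(seq_len(ncol(block)), function(c) block[, c])
  }
  N <- length(lines[[1]])
  ks <- 0:(N %/% 2)
  freq <- ks / (N * spacing)
  avg <- numeric(length(ks))
  for (ln in lines) {
    for (j in seq_along(ks)) {
      k <- ks[j]
      re <- 0; im <- 0
      for (n in 0:(N - 1)) {
        ang <- -2 * pi * k * n / N
        re <- re + ln[n + 1] * cos(ang)
        im <- im + ln[n + 1] * sin(ang)
      }
      avg[j] <- avg[j] + (re^2 + im^2) / N^2
    }
  }
  avg <- avg / length(lines)
  keep <- which(freq >= band[1] & freq <= band[2])
  if (length(keep) < 2) return(0)
  total <- 0
  for (j in seq_len(length(keep) - 1)) {
    a <- keep[j]; b <- keep[j + 1]
    total <- total + (freq[b] - freq[a]) * (avg[a] + avg[b]) / 2
  }
  total
}

# exhaustive distance: for each lung voxel, the minimum Euclidean distance
# (physical units) to any probe-facing boundary voxel
oracle_superficial_region <- function(lung, vox_mm, depth_mm) {
  d <- dim(lung)
  boundary <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lung[x, y, z] && (x == 1 || !lung[x - 1, y, z]))
      boundary[x, y, z] <- TRUE
  }
  bidx <- which(boundary, arr.ind = TRUE)
  region <- array(FALSE, d)
  lidx <- which(lung, arr.ind = TRUE)
  for (i in seq_len(nrow(lidx))) {
    p <- lidx[i, ]
    dx <- (bidx[, 1] - p[1]) * vox_mm[1]
    dy <- (bidx[, 2] - p[2]) * vox_mm[2]
    dz <- (bidx[, 3] - p[3]) * vox_mm[3]
    if (min(sqrt(dx^2 + dy^2 + dz^2)) < depth_mm)
      region[p[1], p[2], p[3]] <- TRUE
  }
  region
}

# textbook OLS via normal equations for a single covariate
oracle_simple_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, residual_sd = sqrt(s2), r2 = r2)
}
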