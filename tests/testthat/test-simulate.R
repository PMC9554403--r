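test_that("clip generation is deterministic and validates inputs", {
  cfg <- tiny_cfg()
  a <- generate_clip(cfg, 0.4, "inflation", seed = 7)
  b <- generate_clip(cfg, 0.4, "inflation", seed = 7)
  expect_identical(a$frames, b$frames)
  c <- generate_clip(cfg, 0.4, "inflation", seed = 8)
  expect_false(identical(a$frames, c$frames))

  expect_error(generate_clip(cfg, -0.1), "air_fraction")
  expect_error(generate_clip(cfg, 1.2), "air_fraction")
  expect_error(simulation_config(grade_thresholds = c(0.5, 0.2, 0.7, 0.9)),
               "increasing")
  expect_error(simulation_config(air_gray_value = 0.2),
               "air_gray_value < air_threshold")
  expect_error(simulation_config(image_height_px = 8), "16 px")
})

test_that("zero air fraction yields a liquid-filled (grade 0) clip with no pleural echo", {
  cfg <- tiny_cfg()
  clip <- generate_clip(cfg, 0, "inflation", seed = 3)
  expect_equal(clip$true_grade, 0)
  pr <- round(cfg$pleural_depth_cm / cfg$pixel_spacing_cm_per_px)
  band <- clip$frames[(pr - 3):(pr + 4), , ]
  expect_true(max(band) < 150)   # tissue texture only, no bright echo
})

test_that("high air fraction yields A-line bands at integer multiples of the pleural depth", {
  cfg <- tiny_cfg()
  clip <- generate_clip(cfg, 0.9, "inflation", seed = 5)
  expect_equal(clip$true_grade, 3)
  prof <- rowMeans(apply(clip$frames, c(1, 2), mean))
  pr <- round(cfg$pleural_depth_cm / cfg$pixel_spacing_cm_per_px)
  for (k in 1:3) {
    band_max <- max(prof[(k * pr):(k * pr + 1)])
    flank <- c(prof[(k * pr - 6):(k * pr - 3)], prof[(k * pr + 4):(k * pr + 7)])
    expect_gt(band_max, max(flank) + 5)
  }
})

test_that("grade labels are the air-fraction bins of the configured thresholds", {
  thr <- c(0, 0.15, 0.5, 0.85)
  expect_equal(grade_from_air_fraction(0, thr), 0)
  expect_equal(grade_from_air_fraction(0.1, thr), 0.5)
  expect_equal(grade_from_air_fraction(0.15, thr), 1)
  expect_equal(grade_from_air_fraction(0.49, thr), 1)
  expect_equal(grade_from_air_fraction(0.5, thr), 2)
  expect_equal(grade_from_air_fraction(0.9, thr), 3)
  cfg <- tiny_cfg()
  for (af in c(0, 0.05, 0.3, 0.6, 0.95)) {
    clip <- generate_clip(cfg, af, seed = 11)
    expect_equal(clip$true_grade, grade_from_air_fraction(af, cfg$grade_thresholds))
  }
})

test_that("CT phantom endpoints and recorded fraction match a per-voxel oracle scan", {
  cfg <- simulation_config()
  ph1 <- generate_ct_phantom(cfg, 1.0, seed = 2)
  region <- superficial_region(ph1, 10)
  expect_true(all(ph1$voxels[region] < cfg$air_threshold))

  ph0 <- generate_ct_phantom(cfg, 0.0, seed = 2)
  expect_identical(sum(ph0$voxels[ph0$lung_mask] < cfg$air_threshold), 0L)

  ph <- generate_ct_phantom(cfg, 0.5, seed = 9)
  region <- superficial_region(ph, 10)
  # independent scan: count voxels below threshold inside the region
  n_air <- 0L; n_reg <- 0L
  vals <- ph$voxels[region]
  for (v in vals) {
    n_reg <- n_reg + 1L
    if (v < cfg$air_threshold) n_air <- n_air + 1L
  }
  expect_equal(ph$true_superficial_air_fraction, n_air / n_reg)
  expect_lt(abs(ph$true_superficial_air_fraction - 0.5), 0.02)
})

test_that("cohorts have the expected size, start deflated, and honour hysteresis", {
  sched <- default_pressure_schedule()
  plan <- lusaer:::cohort_plan(7, sched, seed = 21)
  expect_equal(nrow(plan), 7 * 2 * nrow(sched))

  # pressure 0 at inflation start: no air, grade 0
  start <- plan[plan$phase == "inflation" & plan$pressure_cmH2O == 0, ]
  expect_true(all(start$true_air_fraction == 0))

  # hysteresis: deflation holds at least as much air as inflation at the
  # same pressure, lung by lung
  for (lamb in unique(plan$lamb_id)) for (side in c("left", "right")) {
    lng <- plan[plan$lamb_id == lamb & plan$lung_side == side, ]
    infl <- lng[lng$phase == "inflation", ]
    defl <- lng[lng$phase == "deflation", ]
    for (p in intersect(infl$pressure_cmH2O, defl$pressure_cmH2O)) {
      expect_gte(defl$true_air_fraction[defl$pressure_cmH2O == p],
                 infl$true_air_fraction[infl$pressure_cmH2O == p])
    }
  }

  # median air fraction strictly increasing across observed grades
  g <- grade_from_air_fraction(plan$true_air_fraction)
  med <- tapply(plan$true_air_fraction, g, median)
  expect_true(all(diff(med) > 0))
})

test_that("counting example: 7 lambs on a 12-step schedule give 168 observations", {
  sched <- pressure_schedule(c(0, 15, 20, 25, 30, 35, 40, 50, 40, 25, 10, 0),
                             c(rep("inflation", 8), rep("deflation", 4)))
  plan <- lusaer:::cohort_plan(7, sched, seed = 4)
  expect_equal(nrow(plan), 168)
  expect_error(generate_cohort(0, sched, tiny_cfg()), "n_lambs")
  expect_error(pressure_schedule(numeric(0), character(0)), "at least one")
  expect_error(pressure_schedule(c(10, 20, 15), rep("inflation", 3)),
               "non-decreasing")
})

test_that("generate_cohort returns paired observations with matching ground truth", {
  cfg <- tiny_cfg()
  sched <- pressure_schedule(c(0, 25, 50), rep("inflation", 3))
  obs <- generate_cohort(1, sched, cfg, seed = 5)
  expect_length(obs, 6)
  tab <- cohort_table(obs)
  expect_equal(nrow(tab), 6)
  for (o in obs) {
    expect_s3_class(o$clip, "lus_clip")
    expect_s3_class(o$ct, "ct_volume")
    expect_equal(o$true_grade,
                 grade_from_air_fraction(o$true_air_fraction, cfg$grade_thresholds))
    expect_lt(abs(o$true_ct_superficial_fraction - o$true_air_fraction), 0.021)
  }
  # determinism across full cohorts
  obs2 <- generate_cohort(1, sched, cfg, seed = 5)
  expect_identical(obs[[4]]$clip$frames, obs2[[4]]$clip$frames)
  expect_identical(obs[[4]]$ct$voxels, obs2[[4]]$ct$voxels)
})

test_that("mean pixel intensity rises across grades 0 -> 0.5 -> 1", {
  cfg <- tiny_cfg()
  rois <- default_rois(cfg)
  fc <- feature_config()
  mean_mpi <- function(lo, hi, n = 50) {
    mean(vapply(seq_len(n), function(i) {
      af <- if (hi > lo) lo + (hi - lo) * (i - 0.5) / n else lo
      clip_features(generate_clip(cfg, af, "inflation", seed = 900 + i),
                    rois, fc)$mpi
    }, numeric(1)))
  }
  m0 <- mean_mpi(0, 0)
  m05 <- mean_mpi(0.02, 0.13)
  m1 <- mean_mpi(0.16, 0.48)
  expect_lt(m0, m05)
  expect_lt(m05, m1)
})
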