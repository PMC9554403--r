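test_that("ROI extraction converts depths to rows and enforces bounds", {
  f <- matrix(seq_len(10000), 100, 100)
  # full-frame ROI is the identity
  block <- extract_roi(f, roi_spec(0, 0, depth_cm = 10, width_px = 100), 0.1)
  expect_identical(block, f)
  # 2-cm ROI at 0.01 cm/px has 200 rows
  g <- matrix(0, 300, 40)
  blk <- extract_roi(g, roi_spec(10, 4, depth_cm = 2, width_px = 20), 0.01)
  expect_equal(dim(blk), c(200L, 20L))
  # ROI extending past the bottom row errors
  expect_error(extract_roi(g, roi_spec(150, 0, depth_cm = 2, width_px = 20), 0.01),
               "bounds")
  expect_error(roi_spec(0, 0, 2, width_px = 4), "width_px")
})

test_that("mean pixel intensity matches arithmetic and a pixel-sum oracle", {
  expect_equal(mean_pixel_intensity(matrix(100, 5, 5)), 100)
  expect_equal(mean_pixel_intensity(matrix(c(0, 50, 100, 150), 2, 2)), 75)
  expect_error(mean_pixel_intensity(matrix(numeric(0), 0, 0)), "empty")

  clip <- generate_clip(tiny_cfg(), 0.6, "inflation", seed = 7)
  block <- clip$frames[, , 1]
  expect_equal(mean_pixel_intensity(block), oracle_mean(block),
               tolerance = 1e-12)
})

test_that("coefficient of variation uses the population SD and rejects zero means", {
  expect_equal(coefficient_of_variation(matrix(7, 4, 4)), 0)
  expect_equal(coefficient_of_variation(matrix(c(50, 150), 1, 2)), 0.5)
  expect_error(coefficient_of_variation(matrix(0, 3, 3)), "mean")
  clip <- generate_clip(tiny_cfg(), 0.3, "inflation", seed = 2)
  block <- clip$frames[30:60, 10:40, 2]
  expect_equal(coefficient_of_variation(block), oracle_cov(block),
               tolerance = 1e-12)
})

test_that("directional band power matches a naive DFT oracle and analytic cases", {
  sp <- 0.05
  # constant block: zero power outside DC
  expect_equal(power_spectrum_auc(matrix(9, 16, 16), "parallel",
                                  c(0.1, 2), sp), 0)
  # cosine grating across columns: parallel power matches the slow oracle,
  # perpendicular power is exactly zero
  x <- 0:15
  block <- matrix(rep(100 + 50 * cos(2 * pi * 3 * x / 16), each = 16), 16, 16)
  got <- power_spectrum_auc(block, "parallel", c(0.5, 6), sp)
  want <- oracle_power_auc(block, "parallel", c(0.5, 6), sp)
  expect_gt(got, 0)
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(power_spectrum_auc(block, "perpendicular", c(0.5, 6), sp), 0)
  # random block, both axes
  set.seed(42)
  rb <- matrix(runif(16 * 20, 0, 255), 20, 16)
  for (ax in c("parallel", "perpendicular")) {
    expect_equal(power_spectrum_auc(rb, ax, c(0.4, 8), sp),
                 oracle_power_auc(rb, ax, c(0.4, 8), sp), tolerance = 1e-9)
  }
  # bad bands
  expect_error(power_spectrum_auc(rb, "parallel", c(0, 2), sp), "DC")
  expect_error(power_spectrum_auc(rb, "parallel", c(1, 30), sp), "Nyquist")
  expect_error(power_spectrum_auc(matrix(1, 8, 8), "parallel", c(0.5, 6), sp),
               "16 px")
})

test_that("feature statistics obey their scaling invariances", {
  set.seed(7)
  sp <- 0.05
  for (i in 1:5) {
    b <- matrix(runif(24 * 24, 10, 200), 24, 24)
    a <- runif(1, 0.5, 3)
    expect_equal(mean_pixel_intensity(a * b), a * mean_pixel_intensity(b),
                 tolerance = 1e-12)
    expect_equal(coefficient_of_variation(a * b), coefficient_of_variation(b),
                 tolerance = 1e-12)
    auc <- power_spectrum_auc(b, "parallel", c(0.5, 6), sp)
    expect_equal(power_spectrum_auc(b + 37, "parallel", c(0.5, 6), sp), auc,
                 tolerance = 1e-9 * auc)
    expect_equal(power_spectrum_auc(a * b, "parallel", c(0.5, 6), sp),
                 a^2 * auc, tolerance = 1e-9 * auc)
  }
})

test_that("per-clip pooling is the area-weighted mean of per-ROI frame means", {
  # two same-depth ROIs with areas in ratio 1:3 and MPI 10 vs 20 pool to 17.5
  frame <- cbind(matrix(10, 20, 16), matrix(20, 20, 48))
  clip <- structure(list(frames = array(frame, c(20, 64, 3)),
                         pixel_spacing_cm_per_px = 0.1),
                    class = "lus_clip")
  rois <- list(roi_spec(0, 0, depth_cm = 2, width_px = 16),
               roi_spec(0, 16, depth_cm = 2, width_px = 48))
  feats <- clip_features(clip, rois)
  expect_equal(feats$mpi, 17.5)
  # single ROI: weighted mean equals the plain mean
  feats1 <- clip_features(clip, rois[1])
  expect_equal(feats1$mpi, 10)

  # depth routing: MPI/AUC from 4-cm ROIs, CoV from 2-cm ROIs
  cfg <- tiny_cfg()
  cl <- generate_clip(cfg, 0.55, "inflation", seed = 13)
  rois <- default_rois(cfg)
  depths <- vapply(rois, function(r) r$depth_cm, numeric(1))
  full <- clip_features(cl, rois)
  expect_equal(full$mpi, clip_features(cl, rois[depths == 4])$mpi)
  expect_equal(full$cov, clip_features(cl, rois[depths == 2])$cov)
  expect_error(clip_features(cl, rois[depths != 2],
                             feature_config(cov_depth_cm = 2)), "2 cm")
})

test_that("pooled clip features equal an explicit double-loop oracle", {
  cfg <- tiny_cfg()
  clip <- generate_clip(cfg, 0.7, "deflation", seed = 19)
  rois <- default_rois(cfg)
  fc <- feature_config()
  feats <- clip_features(clip, rois, fc)

  pool <- function(rois_used, statfn) {
    vals <- c(); areas <- c()
    for (roi in rois_used) {
      per_frame <- c()
      for (f in seq_len(dim(clip$frames)[3])) {
        blk <- extract_roi(clip$frames[, , f], roi, cfg$pixel_spacing_cm_per_px)
        per_frame <- c(per_frame, statfn(blk))
      }
      vals <- c(vals, mean(per_frame))
      areas <- c(areas, nrow(extract_roi(clip$frames[, , 1], roi,
                                         cfg$pixel_spacing_cm_per_px)) * roi$width_px)
    }
    sum(vals * areas) / sum(areas)
  }
  depths <- vapply(rois, function(r) r$depth_cm, numeric(1))
  expect_equal(feats$mpi, pool(rois[depths == 4], oracle_mean),
               tolerance = 1e-12)
  expect_equal(feats$cov, pool(rois[depths == 2], oracle_cov),
               tolerance = 1e-12)
  sp <- cfg$pixel_spacing_cm_per_px
  expect_equal(feats$auc_perpendicular,
               pool(rois[depths == 4], function(b)
                 power_spectrum_auc(b, "perpendicular",
                                    fc$band_cycles_per_cm, sp)),
               tolerance = 1e-12)

  # frame order does not change pooled features
  perm <- clip
  perm$frames <- clip$frames[, , c(3, 1, 5, 2, 4)]
  expect_equal(clip_features(perm, rois, fc), feats)
})

test_that("each image statistic tracks true air fraction over the type-1/2 range", {
  cfg <- tiny_cfg()
  rois <- default_rois(cfg)
  fc <- feature_config()
  set.seed(31)
  afs <- runif(100, 0.16, 0.84)
  feats <- t(vapply(seq_along(afs), function(i) {
    cl <- generate_clip(cfg, afs[i], "inflation", seed = 3000 + i)
    unlist(clip_features(cl, rois, fc)[1, 1:4])
  }, numeric(4)))
  for (j in 1:4) {
    ct <- cor.test(afs, feats[, j])
    expect_lt(ct$p.value, 0.05)
  }
  # signs: brightness falls, heterogeneity and B-line band power rise
  expect_lt(cor(afs, feats[, "mpi"]), 0)
  expect_gt(cor(afs, feats[, "cov"]), 0)
  expect_gt(cor(afs, feats[, "auc_parallel"]), 0)
})
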