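test_that("Gaussian-minimum background behaves on constructed rasters", {
  # constant raster: smoothing preserves it
  expect_equal(estimate_background(matrix(123, 16, 16), 5), 123)
  # single pixel: its own value
  expect_equal(estimate_background(matrix(42, 1, 1), 5), 42)

  # flat background + isolated bright spots (<1% of pixels) far from the
  # minimum: estimate within 1 gray level of the flat level
  r <- matrix(100, 128, 128)
  r[20, 20] <- r[20, 40] <- r[40, 20] <- r[30, 30] <- 5000
  bg <- estimate_background(r, sigma_px = 8)
  expect_lt(abs(bg - 100), 1)

  # monotone ramp: background is the smoothed low corner, >= raster minimum
  ramp <- outer(1:32, 1:32, "+") * 10
  sm <- gauss_smooth(ramp, 4)
  bg_ramp <- estimate_background(ramp, 4)
  expect_equal(bg_ramp, sm[1, 1])
  expect_gte(bg_ramp, min(ramp))
})

test_that("Pearson coefficient matches hand-computed and duplicate-channel cases", {
  roi <- data.frame(roi_id = "r1", row0 = 0, col0 = 0, row1 = 2, col1 = 2)
  core <- quad_core(list(matrix(c(1, 2, 3, 4), 2),
                         matrix(c(1, 3, 2, 4), 2),
                         matrix(c(1, 2, 3, 4), 2),
                         matrix(c(5, 9, 2, 6), 2)))
  # covariance 4, variances 5 and 5 -> r = 0.8
  res <- pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "none")
  expect_equal(res$pearson_r, 0.8)
  # identical channels -> r = 1
  res_dup <- pearson_coloc(core, roi, c("WNT4", "CD1"), background = "none")
  expect_equal(res_dup$pearson_r, 1)
  # constant channel -> missing with recorded reason
  core_const <- quad_core(list(matrix(c(1, 2, 3, 4), 2), matrix(5, 2, 2),
                               matrix(1:4, 2), matrix(1:4, 2)))
  res_const <- pearson_coloc(core_const, roi, c("WNT4", "MMP7"),
                             background = "none")
  expect_true(is.na(res_const$pearson_r))
  expect_equal(res_const$reason, "zero variance")
})

test_that("Pearson is symmetric and invariant under positive affine rescaling", {
  set.seed(5)
  roi <- data.frame(roi_id = "r1", row0 = 1, col0 = 2, row1 = 7, col1 = 9)
  a <- matrix(sample.int(5000, 100), 10, 10)
  b <- matrix(sample.int(5000, 100), 10, 10)
  core <- quad_core(list(a, b, a + b, matrix(1:100, 10)))
  r_ab <- pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "none")
  r_ba <- pearson_coloc(core, roi, c("MMP7", "WNT4"), background = "none")
  expect_identical(r_ab$pearson_r, r_ba$pearson_r)
  expect_identical(r_ab$channel_a, "WNT4")        # canonical pair order

  scaled <- quad_core(list(a * 3 + 41, b, a + b, matrix(1:100, 10)))
  r_scaled <- pearson_coloc(scaled, roi, c("WNT4", "MMP7"),
                            background = "none")
  expect_equal(r_scaled$pearson_r, r_ab$pearson_r, tolerance = 1e-9)
})

test_that("Pearson equals a naive two-pass oracle on random ROIs", {
  set.seed(23)
  for (i in 1:100) {
    nr <- sample(2:32, 1); nc <- sample(2:32, 1)
    a <- matrix(rnorm(64 * 64, 500, 100), 64, 64)
    b <- matrix(rnorm(64 * 64, 500, 100), 64, 64)
    b <- b + 0.5 * a
    core <- quad_core(lapply(list(a, b, a, b), function(m)
      round(pmax(m, 0))))
    r0 <- sample(0:(64 - nr), 1); c0 <- sample(0:(64 - nc), 1)
    roi <- data.frame(roi_id = "r", row0 = r0, col0 = c0,
                      row1 = r0 + nr, col1 = c0 + nc)
    res <- pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "none")
    av <- core$channels$WNT4[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)]
    bv <- core$channels$MMP7[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)]
    expect_equal(res$pearson_r, brute_pearson(as.numeric(av), as.numeric(bv)),
                 tolerance = 1e-10)
  }
})

test_that("scalar background subtraction without clamping leaves r unchanged", {
  set.seed(77)
  # bright tissue with a genuinely dark corner that anchors the background
  base_a <- matrix(round(rnorm(400, 3000, 200)), 20, 20)
  base_b <- matrix(round(rnorm(400, 4000, 250)), 20, 20)
  base_a[1:5, 1:5] <- 10
  base_b[1:5, 1:5] <- 25
  core <- quad_core(list(base_a, base_b, base_a, base_b))
  roi <- data.frame(roi_id = "r", row0 = 8, col0 = 8, row1 = 18, col1 = 18)
  plain <- pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "none")
  sub <- pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "subtract")
  expect_equal(sub$clamped_fraction, 0)
  expect_gt(sub$background_a, 0)
  expect_equal(sub$pearson_r, plain$pearson_r, tolerance = 1e-12)
})

test_that("out-of-bounds or empty ROIs are rejected", {
  core <- same_core(matrix(1:16, 4, 4))
  expect_error(pearson_coloc(core, data.frame(roi_id = "r", row0 = 0, col0 = 0,
                                              row1 = 5, col1 = 4),
                             c("WNT4", "MMP7")), "invalid")
  expect_error(pearson_coloc(core, data.frame(roi_id = "r", row0 = 2, col0 = 0,
                                              row1 = 2, col1 = 4),
                             c("WNT4", "MMP7")), "invalid")
  expect_error(pearson_coloc(core, data.frame(roi_id = "r", row0 = 0, col0 = 0,
                                              row1 = 4, col1 = 4),
                             c("WNT4", "WNT4")), "distinct")
})

test_that("cohort co-localization enumerates 6 pairs per ROI in stable order", {
  cfg <- cohort_config(cores_per_group = c(control = 1, gradeI = 1, gradeII = 1),
                       image_size_px = 64, core_radius_px = 24, seed = 4)
  dir <- file.path(tempdir(), "coloc_rows")
  unlink(dir, recursive = TRUE)
  man <- simulate_cohort(cfg, dir)
  rois <- do.call(rbind, lapply(1:4, function(i)
    data.frame(core_id = man$core_id[1], roi_id = sprintf("roi%02d", i),
               row0 = 16 + 4 * i, col0 = 20, row1 = 24 + 4 * i, col1 = 28)))
  tab <- coloc_cohort(man, rois, background = "none")
  expect_equal(nrow(tab), 24)                      # 6 pairs x 4 ROIs
  expect_equal(unique(paste(tab$channel_a, tab$channel_b)),
               paste(channel_pairs()[, 1], channel_pairs()[, 2]))
  expect_error(coloc_cohort(man, transform(rois, core_id = "nope")),
               "absent from manifest")
})

test_that("generator-to-estimator loop recovers ROI-level correlation", {
  # short spatial correlation so each 32x32 ROI holds many independent
  # patches; ROI-level r then estimates the target tightly
  R <- pair_cor(1, 2, 0.7)
  cfg <- cohort_config(cores_per_group = c(control = 1, gradeI = 1, gradeII = 1),
                       correlation = list(control = R, gradeI = R, gradeII = R),
                       smoothing_length = 1, noise_sd = 0, seed = 19)
  core <- simulate_core(cfg, "gradeI", 1)
  rois <- roi_grid(core, roi_size = 32, max_rois = 8)
  expect_gte(nrow(rois), 8)
  res <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    pearson_coloc(core, rois[i, ], c("WNT4", "MMP7"), background = "none")))
  expect_gt(mean(res$pearson_r), 0.6)
  expect_lt(mean(res$pearson_r), 0.8)

  # identity correlation: all six pair means near zero
  cfg0 <- cohort_config(cores_per_group = c(control = 1, gradeI = 1,
                                            gradeII = 1),
                        smoothing_length = 1, noise_sd = 0, seed = 19)
  core0 <- simulate_core(cfg0, "gradeI", 1)
  rois0 <- roi_grid(core0, roi_size = 32, max_rois = 8)
  pairs <- channel_pairs()
  for (p in seq_len(nrow(pairs))) {
    res0 <- do.call(rbind, lapply(seq_len(nrow(rois0)), function(i)
      pearson_coloc(core0, rois0[i, ], pairs[p, ], background = "none")))
    expect_lt(abs(mean(res0$pearson_r)), 0.1)
  }
})
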