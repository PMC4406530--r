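test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 11)
  a <- simulate_core(cfg, "gradeI", 2)
  b <- simulate_core(cfg, "gradeI", 2)
  expect_identical(a$channels, b$channels)
  c2 <- simulate_core(cfg, "gradeI", 3)
  expect_false(identical(a$channels, c2$channels))
  other_seed <- simulate_core(tiny_cfg(seed = 12), "gradeI", 2)
  expect_false(identical(a$channels, other_seed$channels))
})

test_that("pixel values are integers within the 16-bit range", {
  core <- simulate_core(tiny_cfg(seed = 3), "control", 1)
  for (ch in tma_channels()) {
    v <- core$channels[[ch]]
    expect_type(v, "integer")
    expect_gte(min(v), 0)
    expect_lte(max(v), 65535)
  }
})

test_that("disc mask area matches pi r^2 within 1% for r >= 50", {
  for (spec in list(c(128, 50), c(256, 110), c(512, 200))) {
    n <- spec[1]; r <- spec[2]
    area <- sum(disc_mask(n, r))
    expect_lt(abs(area - pi * r^2) / (pi * r^2), 0.01)
  }
})

test_that("independent channels without smoothing or noise recover configured means", {
  ch <- tma_channels()
  cp <- data.frame(group = "g", channel = ch,
                   mean = c(2000, 3000, 4000, 5000), sd = 0)
  cfg <- cohort_config(groups = "g", cores_per_group = c(g = 1),
                       channel_params = cp, smoothing_length = 0,
                       noise_sd = 0, image_size_px = 128, core_radius_px = 55,
                       seed = 5)
  core <- simulate_core(cfg, "g", 1)
  mask <- disc_mask(128, 55)
  mus <- vapply(ch, function(k) mean(core$channels[[k]][mask]), numeric(1))
  expect_true(all(abs(mus - cp$mean) < 1))       # quantization only
  for (i in 1:3) for (j in (i + 1):4) {
    r <- cor(as.numeric(core$channels[[ch[i]]][mask]),
             as.numeric(core$channels[[ch[j]]][mask]))
    expect_lt(abs(r), 0.01)
  }
})

test_that("target inter-channel correlation is recovered at >= 1e4 mask pixels", {
  R <- pair_cor(1, 2, 0.7)                       # r(WNT4, MMP7) = 0.7
  for (seed in 1:20) {
    cfg <- cohort_config(
      cores_per_group = c(control = 1, gradeI = 1, gradeII = 1),
      correlation = list(control = R, gradeI = R, gradeII = R),
      seed = seed)
    core <- simulate_core(cfg, "gradeI", 1)
    mask <- disc_mask(cfg$image_size_px, cfg$core_radius_px)
    expect_gte(sum(mask), 1e4)
    r_emp <- cor(as.numeric(core$channels$WNT4[mask]),
                 as.numeric(core$channels$MMP7[mask]))
    expect_gte(r_emp, 0.65)
    expect_lte(r_emp, 0.75)
  }
})

test_that("group means of per-core within-mask means match the truncated-normal expectation", {
  cfg <- cohort_config(cores_per_group = c(control = 25, gradeI = 1,
                                           gradeII = 1),
                       seed = 21)
  mask <- disc_mask(cfg$image_size_px, cfg$core_radius_px)
  cp <- cfg$channel_params
  for (ch in tma_channels()) {
    mus <- vapply(1:25, function(i)
      mean(simulate_core(cfg, "control", i)$channels[[ch]][mask]), numeric(1))
    row <- cp[cp$group == "control" & cp$channel == ch, ]
    expected <- truncnorm_mean(row$mean, row$sd)   # truncation at 0 shifts up
    expect_lt(abs(mean(mus) - expected), 3 * row$sd / sqrt(25))
  }
})

test_that("invalid correlation matrices are rejected with the offending group named", {
  bad_psd <- matrix(c(1, 0.9, 0.9, 0,
                      0.9, 1, -0.9, 0,
                      0.9, -0.9, 1, 0,
                      0, 0, 0, 1), 4, 4)
  expect_error(
    tiny_cfg(correlation = list(control = diag(4), gradeI = bad_psd,
                                gradeII = diag(4))),
    "gradeI.*positive-semidefinite")
  out_of_range <- pair_cor(1, 2, 1.2)
  expect_error(
    tiny_cfg(correlation = list(control = out_of_range, gradeI = diag(4),
                                gradeII = diag(4))),
    "control")
  asym <- diag(4); asym[1, 2] <- 0.5
  expect_error(
    tiny_cfg(correlation = list(control = diag(4), gradeI = diag(4),
                                gradeII = asym)),
    "gradeII.*symmetric")
  no_unit <- diag(4) * 2
  expect_error(
    tiny_cfg(correlation = list(control = no_unit, gradeI = diag(4),
                                gradeII = diag(4))),
    "unit diagonal")
})

test_that("geometry that cannot hold the core is rejected", {
  expect_error(cohort_config(core_radius_px = 200, image_size_px = 256),
               "does not fit")
  expect_error(cohort_config(core_radius_px = 1), "too small")
})

test_that("simulated fields match an independent Gaussian filter away from borders", {
  set.seed(7)
  x <- matrix(rnorm(64 * 64, 100, 20), 64, 64)
  mine <- gauss_smooth(x, 3)
  ref <- EBImage::gblur(x, sigma = 3)
  interior <- 17:48
  expect_lt(max(abs(mine[interior, interior] - ref[interior, interior])), 0.1)
  # constant preserved exactly
  expect_equal(gauss_smooth(matrix(5, 20, 20), 4), matrix(5, 20, 20),
               tolerance = 1e-12)
})

test_that("simulate_cohort writes one TIFF per core and a round-tripping manifest", {
  cfg <- cohort_config(cores_per_group = c(control = 1, gradeI = 1, gradeII = 1),
                       image_size_px = 64, core_radius_px = 24, seed = 9)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  man <- simulate_cohort(cfg, dir)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$path)))
  expect_setequal(man$group, c("control", "gradeI", "gradeII"))
  rt <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(rt$core_id, man$core_id)
  expect_equal(rt$path, man$path)
  md5_first <- tools::md5sum(sort(man$path))
  man2 <- simulate_cohort(cfg, dir)               # rerun, same seed, same dir
  expect_identical(unname(md5_first), unname(tools::md5sum(sort(man2$path))))
})

test_that("default cohort configuration mirrors the study: 137 cores from 101 patients", {
  cfg <- cohort_config()
  expect_equal(unname(cfg$cores_per_group), c(37L, 82L, 18L))
  expect_equal(sum(cfg$cores_per_group), 137L)
  expect_equal(sum(cfg$patients_per_group), 101L)
})
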