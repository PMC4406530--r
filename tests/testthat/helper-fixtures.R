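# fixtures are built in code; no binary test data

# core with the same raster in all four channels
same_core <- function(m, core_id = "c1", group = "control") {
  core_image(setNames(rep(list(m), 4), tma_channels()),
             core_id = core_id, group = group)
}

# core with four distinct rasters (list in canonical channel order)
quad_core <- function(mats, core_id = "c1", group = "control") {
  core_image(setNames(mats, tma_channels()), core_id = core_id, group = group)
}

# small fast cohort configuration
tiny_cfg <- function(...) {
  cohort_config(cores_per_group = c(control = 3, gradeI = 3, gradeII = 3),
                image_size_px = 96, core_radius_px = 40, ...)
}

# correlation matrix with a single nonzero off-diagonal pair
pair_cor <- function(i, j, r) {
  R <- diag(4)
  R[i, j] <- R[j, i] <- r
  R
}

# naive two-pass Pearson: means first, then explicit sums
brute_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# per-pixel segmentation oracle: explicit loop
brute_quant <- function(m, lo, hi) {
  vals <- c()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]
    if (v >= lo && v <= hi) vals <- c(vals, v)
  }
  list(n = length(vals),
       mean = if (length(vals)) mean(vals) else NA_real_,
       sum = if (length(vals)) sum(vals) else NA_real_)
}

# mean of a normal truncated below at 0
truncnorm_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}
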