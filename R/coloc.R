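#' Gaussian-minimum background estimate
#'
#' Estimates a scalar background level for one channel as the minimum of the
#' Gaussian-smoothed raster ("Gaussian minimum"): smoothing suppresses
#' isolated bright or dark pixels so the minimum tracks the flat background
#' rather than noise extremes.
#'
#' @param channel_raster Numeric matrix of gray levels.
#' @param sigma_px Smoothing scale in pixels (> 0).
#' @return Background level in gray levels.
#' @export
#' @examples
#' r <- matrix(100, 32, 32); r[16, 16] <- 60000
#' estimate_background(r, sigma_px = 5)  # ~100, the bright spot is smoothed out
estimate_background <- function(channel_raster, sigma_px = 5) {
  stopifnot(is.matrix(channel_raster), length(channel_raster) >= 1,
            sigma_px > 0)
  if (length(channel_raster) == 1L) return(as.numeric(channel_raster[1]))
  min(gauss_smooth(matrix(as.numeric(channel_raster),
                          nrow(channel_raster)), sigma_px))
}

# canonical unordered pair label, ordered by channel position
canonical_pair <- function(pair) {
  idx <- match(pair, tma_channels())
  if (anyNA(idx)) stop("unknown channel in pair: ", paste(pair, collapse = ", "))
  if (idx[1] == idx[2]) stop("pair members must be distinct channels")
  tma_channels()[sort(idx)]
}

#' All six unordered channel pairs
#' @return 6x2 character matrix of channel pairs in canonical order.
#' @export
channel_pairs <- function() t(combn(tma_channels(), 2))

check_roi <- function(roi, dims) {
  with(roi, {
    if (row0 < 0 || col0 < 0 || row1 > dims[1] || col1 > dims[2] ||
        row1 <= row0 || col1 <= col0)
      stop("ROI [", row0, ",", col0, ")x[", row1, ",", col1,
           ") invalid for a ", dims[1], "x", dims[2], " image")
  })
  invisible(roi)
}

#' Pearson co-localization within one ROI
#'
#' Crops both channels of a pair to a rectangular region of interest,
#' optionally subtracts a per-channel scalar background (the Gaussian minimum
#' of the full channel, negative results clamped to zero) and computes the
#' sample Pearson correlation over the ROI pixels. A zero-variance channel in
#' the ROI yields a missing coefficient with a recorded reason.
#'
#' @param core A [core_image()].
#' @param roi One-row data.frame (or list) with `roi_id` and the rectangle
#'   `row0, col0, row1, col1` (0-based, half-open).
#' @param pair Character vector of two distinct channel labels.
#' @param background `"subtract"` (default) or `"none"`.
#' @param sigma_px Smoothing scale of the background estimate, pixels.
#' @return One-row data.frame: `core_id, group, roi_id, channel_a, channel_b,
#'   pearson_r, background_a, background_b, clamped_fraction, reason`.
#' @export
#' @examples
#' ch <- setNames(lapply(1:4, function(i) matrix((1:16) * i, 4, 4)),
#'                tma_channels())
#' core <- core_image(ch, "c1")
#' roi <- data.frame(roi_id = "r1", row0 = 0, col0 = 0, row1 = 4, col1 = 4)
#' pearson_coloc(core, roi, c("WNT4", "MMP7"), background = "none")
pearson_coloc <- function(core, roi, pair,
                          background = c("subtract", "none"), sigma_px = 5) {
  stopifnot(inherits(core, "core_image"))
  background <- match.arg(background)
  pair <- canonical_pair(pair)
  dims <- dim(core$channels[[1]])
  check_roi(roi, dims)

  crop <- function(ch) {
    m <- core$channels[[ch]]
    m[(roi$row0 + 1):roi$row1, (roi$col0 + 1):roi$col1, drop = FALSE]
  }
  a <- as.numeric(crop(pair[1])); b <- as.numeric(crop(pair[2]))
  bg_a <- bg_b <- 0; clamped <- 0
  if (background == "subtract") {
    bg_a <- estimate_background(core$channels[[pair[1]]], sigma_px)
    bg_b <- estimate_background(core$channels[[pair[2]]], sigma_px)
    a <- a - bg_a; b <- b - bg_b
    clamped <- mean(a < 0 | b < 0)
    a <- pmax(a, 0); b <- pmax(b, 0)
  }
  r <- NA_real_; reason <- ""
  if (sd(a) == 0 || sd(b) == 0) reason <- "zero variance"
  else r <- cor(a, b)
  data.frame(core_id = core$core_id, group = core$group,
             roi_id = as.character(roi$roi_id),
             channel_a = pair[1], channel_b = pair[2],
             pearson_r = r, background_a = bg_a, background_b = bg_b,
             clamped_fraction = clamped, reason = reason)
}

#' Grid placement of ROIs inside the tissue area
#'
#' Deterministic stand-in for the study's manual (pathologist-guided) ROI
#' placement: square ROIs are laid on a regular grid and kept when at least
#' `min_tissue` of their pixels exceed an Otsu tissue/background split of the
#' channel-mean image.
#'
#' @param core A [core_image()].
#' @param roi_size ROI side length in pixels.
#' @param max_rois Maximum number of ROIs returned (row-major order); the
#'   study analysed 4-16 ROIs per image.
#' @param min_tissue Minimum within-ROI tissue fraction.
#' @return data.frame `core_id, roi_id, row0, col0, row1, col1` (0-based,
#'   half-open), possibly empty.
#' @export
roi_grid <- function(core, roi_size = 32, max_rois = 8, min_tissue = 0.99) {
  stopifnot(inherits(core, "core_image"), roi_size >= 2)
  avg <- Reduce(`+`, lapply(core$channels, function(m) m / 4))
  tissue <- avg > otsu_floor(as.vector(avg))
  dims <- dim(avg)
  starts_r <- seq(0, dims[1] - roi_size, by = roi_size)
  starts_c <- seq(0, dims[2] - roi_size, by = roi_size)
  rows <- list()
  for (r0 in starts_r) for (c0 in starts_c) {
    frac <- mean(tissue[(r0 + 1):(r0 + roi_size), (c0 + 1):(c0 + roi_size)])
    if (frac >= min_tissue) {
      rows[[length(rows) + 1L]] <- data.frame(
        core_id = core$core_id, roi_id = sprintf("roi%02d", length(rows) + 1L),
        row0 = r0, col0 = c0, row1 = r0 + roi_size, col1 = c0 + roi_size)
    }
    if (length(rows) >= max_rois) break
  }
  if (!length(rows))
    return(data.frame(core_id = character(), roi_id = character(),
                      row0 = integer(), col0 = integer(),
                      row1 = integer(), col1 = integer()))
  out <- do.call(rbind, rows)
  out[seq_len(min(nrow(out), max_rois)), ]
}

#' Cohort-level co-localization
#'
#' Computes [pearson_coloc()] for every (core, ROI, channel pair)
#' combination: 6 pairs per ROI. Cores whose image cannot be read are
#' skipped with a warning.
#'
#' @param manifest Cohort manifest (columns `core_id, group, path`).
#' @param roi_table ROI table (columns `core_id, roi_id, row0, col0, row1,
#'   col1`); ROIs must reference manifest cores.
#' @param background,sigma_px Passed to [pearson_coloc()].
#' @return data.frame, one row per (core, ROI, pair), ordered by
#'   `(core_id, roi_id, pair)`.
#' @export
coloc_cohort <- function(manifest, roi_table,
                         background = c("subtract", "none"), sigma_px = 5) {
  background <- match.arg(background)
  stopifnot(is.data.frame(manifest), is.data.frame(roi_table))
  unknown <- setdiff(roi_table$core_id, manifest$core_id)
  if (length(unknown))
    stop("ROIs reference cores absent from manifest: ",
         paste(unique(unknown), collapse = ", "))
  pairs <- channel_pairs()
  out <- list()
  for (cid in unique(roi_table$core_id)) {
    m <- manifest[manifest$core_id == cid, ][1, ]
    core <- tryCatch(read_core_image(m$path, core_id = cid, group = m$group),
                     error = function(e) {
                       warning("skipping core ", cid, ": ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
    if (is.null(core)) next
    rois <- roi_table[roi_table$core_id == cid, ]
    for (j in seq_len(nrow(rois))) {
      for (p in seq_len(nrow(pairs))) {
        out[[length(out) + 1L]] <-
          pearson_coloc(core, rois[j, ], pairs[p, ],
                        background = background, sigma_px = sigma_px)
      }
    }
  }
  if (!length(out))
    return(data.frame(core_id = character(), group = character(),
                      roi_id = character(), channel_a = character(),
                      channel_b = character(), pearson_r = numeric(),
                      background_a = numeric(), background_b = numeric(),
                      clamped_fraction = numeric(), reason = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$core_id, res$roi_id,
                   match(res$channel_a, tma_channels()),
                   match(res$channel_b, tma_channels())), ]
  rownames(res) <- NULL
  res
}
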