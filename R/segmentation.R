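#' Per-channel segmentation thresholds
#'
#' Container for lower/upper gray-value segmentation bounds per channel.
#'
#' @param lower,upper Named numeric vectors (names in [tma_channels()]), with
#'   `0 <= lower <= upper <= 65535` per channel. Scalars are recycled to all
#'   four channels.
#' @param calibration_core_ids Optional provenance: ids of the cores the
#'   thresholds were calibrated on.
#' @return An object of class `threshold_spec`: a data.frame with columns
#'   `channel`, `lower`, `upper`.
#' @export
#' @examples
#' threshold_spec(lower = 500, upper = 65535)
threshold_spec <- function(lower, upper, calibration_core_ids = character()) {
  ch <- tma_channels()
  if (length(lower) == 1L) lower <- setNames(rep(lower, 4), ch)
  if (length(upper) == 1L) upper <- setNames(rep(upper, 4), ch)
  if (!setequal(names(lower), ch) || !setequal(names(upper), ch))
    stop("lower and upper must be named by the four channels")
  lower <- lower[ch]; upper <- upper[ch]
  if (any(lower < 0) || any(upper > GRAY_MAX) || any(lower > upper))
    stop("thresholds must satisfy 0 <= lower <= upper <= ", GRAY_MAX)
  structure(
    data.frame(channel = ch, lower = as.numeric(lower),
               upper = as.numeric(upper), row.names = NULL),
    calibration_core_ids = calibration_core_ids,
    class = c("threshold_spec", "data.frame"))
}

#' Full-range (no-op) thresholds
#'
#' Thresholds spanning the whole 16-bit range, so that segmentation keeps
#' every pixel and `mean_gray` reduces to the plain arithmetic mean.
#'
#' @return A [threshold_spec()].
#' @export
full_range_thresholds <- function() threshold_spec(0, GRAY_MAX)

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec>\n")
  print.data.frame(x, row.names = FALSE)
  ids <- attr(x, "calibration_core_ids")
  if (length(ids)) cat("calibrated on", length(ids), "core(s)\n")
  invisible(x)
}

# Otsu split of pooled pixel values (gray levels); the background floor used
# to restrict calibration to tissue pixels.
otsu_floor <- function(values) {
  side <- ceiling(sqrt(length(values)))
  m <- matrix(0, side, side)
  m[seq_along(values)] <- values / GRAY_MAX
  GRAY_MAX * EBImage::otsu(m, range = c(0, 1), levels = 65536L)
}

#' Calibrate segmentation thresholds from a sample of cores
#'
#' Implements median-to-maximum calibration: for each channel, pixels of all
#' calibration cores are pooled (restricted to tissue by a background floor),
#' the lower threshold is the pooled median and the upper threshold the
#' pooled maximum. With an even pixel count the median is the mean of the two
#' middle values.
#'
#' @param calibration_cores List of [core_image()] objects (>= 1).
#' @param channels Channels to calibrate (default all four).
#' @param background_floor `"otsu"` (default) to drop pixels at or below an
#'   Otsu split of the pooled histogram — a stand-in for restricting
#'   quantification to tissue — `"none"` to pool all pixels, or a numeric
#'   gray-level floor.
#' @return A [threshold_spec()].
#' @export
#' @examples
#' ch <- setNames(lapply(1:4, function(i) matrix(0:99, 10, 10)), tma_channels())
#' core <- core_image(ch, "cal1")
#' calibrate_thresholds(list(core), background_floor = "none")
calibrate_thresholds <- function(calibration_cores, channels = tma_channels(),
                                 background_floor = "otsu") {
  if (!length(calibration_cores)) stop("need at least one calibration core")
  stopifnot(all(vapply(calibration_cores, inherits, logical(1), "core_image")))
  lower <- upper <- setNames(rep(NA_real_, 4), tma_channels())
  for (ch in channels) {
    pooled <- unlist(lapply(calibration_cores, function(core) {
      if (is.null(core$channels[[ch]])) stop("channel ", ch, " absent in core ",
                                             core$core_id)
      as.vector(core$channels[[ch]])
    }), use.names = FALSE)
    floor_val <-
      if (identical(background_floor, "none")) -Inf
      else if (is.numeric(background_floor)) background_floor
      else otsu_floor(pooled)
    pooled <- pooled[pooled > floor_val]
    if (!length(pooled))
      stop("empty pixel pool for channel ", ch,
           " after background floor ", format(floor_val, digits = 4))
    lower[ch] <- median(pooled)
    upper[ch] <- max(pooled)
  }
  keep <- !is.na(lower)
  full <- threshold_spec(ifelse(keep, lower, 0),
                         ifelse(keep, upper, GRAY_MAX),
                         calibration_core_ids =
                           vapply(calibration_cores, `[[`, character(1),
                                  "core_id"))
  full
}

#' Quantify one core by threshold segmentation
#'
#' For each channel, pixels with `lower <= value <= upper` are segmented;
#' `mean_gray` is the mean gray value over segmented pixels,
#' `integrated_per_area` the segmented intensity sum divided by segmented
#' area (pixel units, or um^2 when `pixel_size_um` is set on the core). A
#' channel with no segmented pixel yields `NA` summaries (flagged, not zero).
#'
#' @param core A [core_image()].
#' @param thresholds A [threshold_spec()] covering all four channels.
#' @return data.frame with one row per channel: `core_id, group, channel,
#'   mean_gray, integrated_per_area, segmented_px, segmented_fraction`.
#' @export
#' @examples
#' ch <- setNames(lapply(1:4, function(i) matrix(1:9, 3, 3)), tma_channels())
#' quantify_core(core_image(ch, "c1"), threshold_spec(4, 8))
quantify_core <- function(core, thresholds) {
  stopifnot(inherits(core, "core_image"), inherits(thresholds, "threshold_spec"))
  px_area <- if (is.null(core$pixel_size_um)) 1 else core$pixel_size_um^2
  ch <- tma_channels()
  npx <- integer(4); s <- numeric(4); ntot <- length(core$channels[[1]])
  for (k in 1:4) {
    v <- core$channels[[ch[k]]]
    th <- thresholds[thresholds$channel == ch[k], ]
    sel <- v >= th$lower & v <= th$upper
    npx[k] <- sum(sel)
    s[k] <- if (npx[k]) sum(as.numeric(v[sel])) else NA_real_
  }
  data.frame(core_id = core$core_id, group = core$group, channel = ch,
             mean_gray = ifelse(npx > 0, s / npx, NA_real_),
             integrated_per_area = ifelse(npx > 0, s / (npx * px_area),
                                          NA_real_),
             segmented_px = npx,
             segmented_fraction = npx / ntot)
}

#' Batch quantification of a cohort
#'
#' Reads every core listed in a manifest and applies [quantify_core()].
#' Unreadable or malformed images are skipped with a warning; the batch
#' continues.
#'
#' @param manifest Cohort manifest data.frame (columns `core_id`, `group`,
#'   `path`) as written by [simulate_cohort()].
#' @param thresholds A [threshold_spec()].
#' @return data.frame with 4 rows (one per channel) per successfully read
#'   core, ordered by `(core_id, channel)`; skipped cores are recorded in
#'   attribute `"errors"`.
#' @export
batch_quantify <- function(manifest, thresholds) {
  stopifnot(is.data.frame(manifest))
  if (!nrow(manifest)) {
    warning("empty manifest: no cores to quantify")
    return(data.frame(core_id = character(), group = character(),
                      channel = character(), mean_gray = numeric(),
                      integrated_per_area = numeric(),
                      segmented_px = integer(), segmented_fraction = numeric()))
  }
  errors <- character()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    tryCatch({
      core <- read_core_image(m$path, core_id = m$core_id, group = m$group)
      quantify_core(core, thresholds)
    }, error = function(e) {
      errors[[m$core_id]] <<- conditionMessage(e)
      warning("skipping core ", m$core_id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (nrow(out)) {
    out <- out[order(out$core_id, match(out$channel, tma_channels())), ]
    rownames(out) <- NULL
  }
  attr(out, "errors") <- errors
  out
}
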