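#' Construct a TMA core image
#'
#' A `core_image` holds one tissue-microarray core: four 2-D integer rasters
#' (16-bit gray levels), one per fluorophore channel, plus identity and
#' tissue-class metadata.
#'
#' @param channels Named list of four integer/numeric matrices with identical
#'   dimensions, names exactly [tma_channels()] (any order; stored in
#'   canonical order). Values must lie in `[0, 65535]`.
#' @param core_id Core identifier (scalar character).
#' @param group Tissue-class label, e.g. `"control"`, `"gradeI"`, `"gradeII"`.
#' @param patient_id Optional patient/sample identifier.
#' @param pixel_size_um Optional physical pixel size in micrometres.
#' @return An object of class `core_image`.
#' @export
#' @examples
#' ch <- setNames(replicate(4, matrix(100L, 8, 8), simplify = FALSE),
#'                tma_channels())
#' core_image(ch, core_id = "demo", group = "control")
core_image <- function(channels, core_id, group = NA_character_,
                       patient_id = NA_character_, pixel_size_um = NULL) {
  stopifnot(is.list(channels), is.character(core_id), length(core_id) == 1L)
  want <- tma_channels()
  if (!setequal(names(channels), want)) {
    stop("channels must be named exactly {", paste(want, collapse = ", "),
         "}; got {", paste(names(channels), collapse = ", "), "}")
  }
  channels <- channels[want]
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channel rasters must share identical dimensions")
  }
  for (ch in want) {
    v <- channels[[ch]]
    if (!is.matrix(v)) stop("channel ", ch, " is not a matrix")
    if (anyNA(v) || min(v) < 0 || max(v) > GRAY_MAX) {
      stop("channel ", ch, " has values outside [0, ", GRAY_MAX, "]")
    }
    storage.mode(channels[[ch]]) <- "integer"
  }
  structure(
    list(core_id = core_id, group = as.character(group),
         patient_id = as.character(patient_id),
         pixel_size_um = pixel_size_um, channels = channels),
    class = "core_image")
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<core_image> %s  group=%s  %dx%d px, 4 channels (%s)\n",
              x$core_id, x$group, d[1], d[2],
              paste(tma_channels(), collapse = ", ")))
  rng <- vapply(x$channels, function(m) range(m), numeric(2))
  for (ch in tma_channels()) {
    cat(sprintf("  %-5s gray range [%d, %d], mean %.1f\n", ch,
                rng[1, ch], rng[2, ch], mean(x$channels[[ch]])))
  }
  invisible(x)
}

#' @export
plot.core_image <- function(x, channels = tma_channels(), ...) {
  op <- par(mfrow = c(ceiling(length(channels) / 2), min(2, length(channels))),
            mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (ch in channels) {
    m <- x$channels[[ch]]
    image(t(m[nrow(m):1, , drop = FALSE]), col = gray.colors(256, 0, 1),
          axes = FALSE, useRaster = TRUE, ...)
    title(sprintf("%s — %s", x$core_id, ch))
  }
  invisible(x)
}

#' Circular tissue mask of a synthetic core
#'
#' Logical matrix marking pixels within `radius` of the image centre
#' (pixel-centre convention).
#'
#' @param n Image side length in pixels.
#' @param radius Disc radius in pixels.
#' @return `n` by `n` logical matrix.
#' @export
disc_mask <- function(n, radius) {
  stopifnot(n >= 1, radius > 0)
  ctr <- (n + 1) / 2
  dx <- (seq_len(n) - ctr)^2
  outer(dx, dx, "+") <= radius^2
}

# mask plus integer pixel indices, cached (simulation hot path)
.mask_cache <- new.env(parent = emptyenv())
disc_mask_idx <- function(n, radius) {
  key <- sprintf("%d_%g", n, radius)
  m <- .mask_cache[[key]]
  if (is.null(m)) {
    mask <- disc_mask(n, radius)
    m <- list(mask = mask, idx = which(mask), idx_bg = which(!mask))
    .mask_cache[[key]] <- m
  }
  m
}
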