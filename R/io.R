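#' Write a core image as multi-page 16-bit TIFF
#'
#' Pages are written in the canonical channel order (WNT4, MMP7, CD1, cMYC).
#'
#' @param core A [core_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_core_image <- function(core, path) {
  stopifnot(inherits(core, "core_image"))
  pages <- lapply(core$channels, function(m) m / GRAY_MAX)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF as a core image
#'
#' Validates that the file has exactly four 16-bit grayscale pages and maps
#' them to channels in canonical order (WNT4, MMP7, CD1, cMYC).
#'
#' @param path TIFF file path.
#' @param core_id,group,patient_id Metadata attached to the returned object
#'   (`core_id` defaults to the file name).
#' @return A [core_image()].
#' @export
read_core_image <- function(path, core_id = NULL, group = NA_character_,
                            patient_id = NA_character_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  meta <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = TRUE),
                   error = function(e)
                     stop("unreadable TIFF '", path, "': ",
                          conditionMessage(e)))
  n_pages <- if (is.data.frame(meta)) nrow(meta) else length(meta)
  if (n_pages != 4L)
    stop("expected 4 pages (one per channel) in '", path, "', found ",
         n_pages)
  bits <- if (is.data.frame(meta)) as.integer(meta$bits.per.sample)
          else vapply(meta, function(m) as.integer(m$bits.per.sample[1]),
                      integer(1))
  if (any(bits != 16L))
    stop("expected 16-bit data in '", path, "', found ",
         paste(unique(bits), collapse = "/"),
         "-bit; convert to 16-bit gray levels before analysis")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  channels <- setNames(pages, tma_channels())
  if (is.null(core_id))
    core_id <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  core_image(channels, core_id = core_id, group = group,
             patient_id = patient_id)
}

#' Maximum-intensity projection of an image stack
#'
#' Reduces a z-stack (list of equal-sized matrices, or a 3-D array with the
#' third dimension indexing planes) to a single plane by the pixelwise
#' maximum. Confocal stacks should be projected with this before entering
#' the single-plane analysis; deconvolution is out of scope.
#'
#' @param stack List of numeric matrices, or a 3-D array.
#' @return A single matrix of pixelwise maxima.
#' @export
#' @examples
#' max_project(list(matrix(1:4, 2), matrix(4:1, 2)))
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  stopifnot(is.list(stack), length(stack) >= 1,
            all(vapply(stack, is.matrix, logical(1))))
  Reduce(pmax, stack)
}

#' Write / read a cohort manifest
#'
#' CSV with header `core_id,group,patient_id,path,seed`, UTF-8, '.' decimal,
#' missing values as empty fields.
#'
#' @param manifest data.frame with the manifest columns.
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the manifest
#'   data.frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("core_id", "group", "patient_id", "path", "seed")
  stopifnot(all(need %in% names(manifest)))
  write.csv(manifest[need], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "group", "path")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(man$core_id)) stop("duplicate core ids in manifest")
  man
}

#' Write / read a threshold specification as YAML
#' @param thresholds A [threshold_spec()].
#' @param path YAML file path.
#' @return `write_thresholds`: `path` invisibly; `read_thresholds`: a
#'   [threshold_spec()].
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_spec"))
  obj <- lapply(seq_len(nrow(thresholds)), function(i)
    list(lower = thresholds$lower[i], upper = thresholds$upper[i]))
  names(obj) <- thresholds$channel
  yaml::write_yaml(list(thresholds = obj,
                        calibration_core_ids =
                          as.list(attr(thresholds, "calibration_core_ids"))),
                   path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  obj <- yaml::read_yaml(path)
  th <- obj$thresholds
  threshold_spec(lower = vapply(th, `[[`, numeric(1), "lower"),
                 upper = vapply(th, `[[`, numeric(1), "upper"),
                 calibration_core_ids = unlist(obj$calibration_core_ids))
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors [cohort_config()] field names under `cohort:` plus
#' optional `segmentation:` (`calibrate_on`, `background_floor`), `coloc:`
#' (`sigma_px`, `background`, `roi_size`, `max_rois`, `coloc_cores`) and
#' `stats:` (`alpha_grid`) sections. Omitted fields take package defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `cohort: seed`.
#' @return List with elements `cohort` (a [cohort_config()]), `segmentation`,
#'   `coloc`, `stats`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  cargs <- obj$cohort %||% list()
  if (!is.null(cargs$cores_per_group))
    cargs$cores_per_group <- unlist(cargs$cores_per_group)
  if (!is.null(cargs$channel_params))
    cargs$channel_params <- as.data.frame(
      lapply(as.data.frame(do.call(rbind, lapply(cargs$channel_params, as.data.frame))),
             unlist))
  if (!is.null(cargs$correlation))
    cargs$correlation <- lapply(cargs$correlation, function(m)
      matrix(unlist(m), 4, 4))
  if (!is.null(seed)) cargs$seed <- seed
  list(cohort = do.call(cohort_config, cargs),
       segmentation = obj$segmentation %||% list(),
       coloc = obj$coloc %||% list(),
       stats = obj$stats %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulate (or reuse) a cohort, calibrate thresholds, quantify every core,
#' compute ROI co-localization, and contrast the groups. All result tables
#' are written as CSV under `output_dir` together with a run log and a
#' Markdown report; reruns with the same config and seed produce
#' byte-identical tables.
#'
#' @param config A [cohort_config()], or the list returned by
#'   [read_pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @param manifest Optional existing cohort manifest; when `NULL` a cohort is
#'   simulated from `config` into `output_dir/images`.
#' @param calibrate_on `"all"` (default) to calibrate the thresholds on every
#'   core — the published median-to-maximum rule pools "a range of samples
#'   across the whole sample set" — a group label, a vector of core ids, or
#'   `"full_range"` to skip calibration and keep every pixel.
#' @param background_floor Passed to [calibrate_thresholds()].
#' @param coloc_cores Number of cores per group entering co-localization
#'   (the study imaged a subset of cores at high magnification); `Inf` = all.
#' @param roi_size,max_rois,sigma_px,coloc_background ROI and background
#'   settings for [roi_grid()] and [coloc_cohort()].
#' @param contrasts Passed to [compare_intensities()]/[compare_coloc()].
#' @param alpha_grid Significance grid.
#' @return List with the tables (`manifest`, `thresholds`, `quant`, `coloc`,
#'   `intensity_comparisons`, `coloc_comparisons`) and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config = cohort_config(), output_dir,
                         manifest = NULL,
                         calibrate_on = "all",
                         background_floor = "otsu",
                         coloc_cores = 3,
                         roi_size = 32, max_rois = 8,
                         sigma_px = 5,
                         coloc_background = "subtract",
                         contrasts = NULL,
                         alpha_grid = alpha_grid_default) {
  settings <- NULL
  if (is.list(config) && !inherits(config, "cohort_config")) {
    settings <- config
    config <- settings$cohort
    seg <- settings$segmentation
    calibrate_on <- seg$calibrate_on %||% calibrate_on
    background_floor <- seg$background_floor %||% background_floor
    col <- settings$coloc
    sigma_px <- col$sigma_px %||% sigma_px
    coloc_background <- col$background %||% coloc_background
    roi_size <- col$roi_size %||% roi_size
    max_rois <- col$max_rois %||% max_rois
    coloc_cores <- col$coloc_cores %||% coloc_cores
    alpha_grid <- unlist(settings$stats$alpha_grid) %||% alpha_grid
  }
  stopifnot(inherits(config, "cohort_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output dir: ", output_dir)

  if (is.null(manifest)) {
    manifest <- simulate_cohort(config, file.path(output_dir, "images"))
  }

  # thresholds
  if (identical(calibrate_on, "full_range")) {
    thresholds <- full_range_thresholds()
  } else {
    ids <-
      if (identical(calibrate_on, "all")) manifest$core_id
      else if (all(calibrate_on %in% manifest$core_id)) calibrate_on
      else manifest$core_id[manifest$group %in% calibrate_on]
    if (!length(ids)) stop("no calibration cores match '",
                           paste(calibrate_on, collapse = ","), "'")
    cal <- lapply(manifest$path[match(ids, manifest$core_id)],
                  read_core_image)
    thresholds <- calibrate_thresholds(cal, background_floor = background_floor)
  }
  th_path <- file.path(output_dir, "thresholds.yaml")
  write_thresholds(thresholds, th_path)

  quant <- batch_quantify(manifest, thresholds)
  quant_path <- file.path(output_dir, "quant.csv")
  write.csv(quant, quant_path, row.names = FALSE, na = "")

  # co-localization on a per-group subset of cores, grid ROIs
  sel <- unlist(lapply(split(manifest$core_id, manifest$group), function(ids)
    utils::head(ids, coloc_cores)))
  rois <- do.call(rbind, lapply(sel, function(cid) {
    core <- read_core_image(manifest$path[manifest$core_id == cid],
                            core_id = cid)
    roi_grid(core, roi_size = roi_size, max_rois = max_rois)
  }))
  coloc <- coloc_cohort(manifest, rois, background = coloc_background,
                        sigma_px = sigma_px)
  roi_path <- file.path(output_dir, "rois.csv")
  write.csv(rois, roi_path, row.names = FALSE, na = "")
  coloc_path <- file.path(output_dir, "coloc.csv")
  write.csv(coloc, coloc_path, row.names = FALSE, na = "")

  icmp <- compare_intensities(quant, contrasts = contrasts,
                              alpha_grid = alpha_grid)
  ccmp <- compare_coloc(coloc, contrasts = contrasts, alpha_grid = alpha_grid)
  icmp_path <- file.path(output_dir, "comparisons_intensity.csv")
  ccmp_path <- file.path(output_dir, "comparisons_coloc.csv")
  write.csv(icmp, icmp_path, row.names = FALSE, na = "")
  write.csv(ccmp, ccmp_path, row.names = FALSE, na = "")

  report_path <- file.path(output_dir, "report.md")
  write_report(icmp, ccmp, quant, report_path)

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(c(
    paste("tmaquant", as.character(packageVersion("tmaquant"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", config$seed),
    paste("cores", sum(config$cores_per_group)),
    paste("calibrate_on", calibrate_on),
    paste("coloc sigma_px", sigma_px, "background", coloc_background),
    paste("comparisons",
          attr(icmp, "n_comparisons") + attr(ccmp, "n_comparisons"))),
    log_path)

  list(manifest = manifest, thresholds = thresholds, quant = quant,
       coloc = coloc, intensity_comparisons = icmp,
       coloc_comparisons = ccmp,
       paths = c(thresholds = th_path, quant = quant_path, rois = roi_path,
                 coloc = coloc_path, intensity_comparisons = icmp_path,
                 coloc_comparisons = ccmp_path, report = report_path,
                 log = log_path))
}

write_report <- function(icmp, ccmp, quant, path) {
  fmt_p <- function(p) ifelse(p < 1e-4, "<0.0001", signif(p, 2))
  lines <- c(
    "# TMA quantification report", "",
    "## Per-channel intensity contrasts (Mann-Whitney U on per-core mean gray values)",
    "",
    "| measure | groups | n | U | p | fold | medians |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s vs %s | %d/%d | %.1f | %s | %s | %.0f / %.0f |",
            icmp$measure, icmp$group_a, icmp$group_b, icmp$n_a, icmp$n_b,
            icmp$u, fmt_p(icmp$p),
            ifelse(is.na(icmp$fold_change), "-", icmp$fold_change),
            icmp$median_a, icmp$median_b),
    "",
    "## Co-localization contrasts (Mann-Whitney U on per-ROI Pearson r)", "",
    "| pair | groups | n | U | p | median diff |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s vs %s | %d/%d | %.1f | %s | %.3f |",
            ccmp$measure, ccmp$group_a, ccmp$group_b, ccmp$n_a, ccmp$n_b,
            ccmp$u, fmt_p(ccmp$p), ccmp$median_diff),
    "",
    sprintf("%d comparisons reported; no multiple-testing correction applied.",
            nrow(icmp) + nrow(ccmp)))
  writeLines(lines, path)
  invisible(path)
}
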