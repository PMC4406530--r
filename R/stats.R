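#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. For two tie-free groups of at most
#' `exact_max` observations each, the two-sided p-value comes from full
#' enumeration of the permutation distribution of U; otherwise from the
#' normal approximation with tie-corrected variance and continuity
#' correction. U counts pairwise wins of `values_a` over `values_b`
#' (ties count 1/2).
#'
#' @param values_a,values_b Numeric vectors, each nonempty.
#' @param exact_max Largest per-group size for the exact branch (default 8).
#' @return List with `u` (U statistic for group a), `z` (normal deviate; 0
#'   when degenerate), `p` (two-sided), `exact` (logical).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(values_a, values_b, exact_max = 8) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (!n1 || !n2) stop("both groups must be nonempty")
  if (anyNA(values_a) || anyNA(values_b)) stop("missing values not allowed")
  all_v <- c(values_a, values_b)
  r <- rank(all_v)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all_v) > 0
  N <- n1 + n2

  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    # exact permutation distribution of the rank sum
    sums <- colSums(matrix(combn(N, n1), nrow = n1))
    us <- sums - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (N + 1) / 12)
    z <- if (u == mu) 0 else (u - mu - 0.5 * sign(u - mu)) / sig
    return(list(u = u, z = z, p = p, exact = TRUE))
  }

  mu <- n1 * n2 / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sig2 <= 0) return(list(u = u, z = 0, p = 1, exact = FALSE))
  z <- if (u == mu) 0 else (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
  list(u = u, z = z, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

# round half away from zero at `digits` decimals
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Fold change of group means
#'
#' Ratio of the case-group mean to the control-group mean, rounded half away
#' from zero to one decimal (the convention of the published fold-increase
#' column).
#'
#' @param control_values,case_values Numeric vectors; the control mean must
#'   be strictly positive.
#' @param digits Decimals to report (default 1).
#' @return Rounded fold change (case mean / control mean).
#' @export
#' @examples
#' fold_change(2081, 5037)  # 2.4
fold_change <- function(control_values, case_values, digits = 1) {
  mc <- mean(control_values)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be > 0")
  round_half_away(mean(case_values) / mc, digits)
}

alpha_grid_default <- c(0.01, 0.001, 0.0001)

# strictest alpha in the grid with p < alpha, NA if none
significant_at <- function(p, alpha_grid = alpha_grid_default) {
  hit <- alpha_grid[p < alpha_grid]
  if (length(hit)) min(hit) else NA_real_
}

resolve_groups <- function(label, groups_present) {
  if (label %in% groups_present) return(label)
  if (label == "malignant") {
    g <- intersect(c("gradeI", "gradeII", "gradeIII"), groups_present)
    if (!length(g)) stop("no malignant groups present")
    return(g)
  }
  if (!label %in% groups_present) stop("unknown group label '", label, "'")
  label
}

default_contrasts <- function(groups_present) {
  cons <- list()
  if ("control" %in% groups_present &&
      length(intersect(c("gradeI", "gradeII"), groups_present))) {
    cons <- c(cons, list(c("control", "malignant")))
    for (g in intersect(c("gradeI", "gradeII"), groups_present))
      cons <- c(cons, list(c("control", g)))
    if (all(c("gradeI", "gradeII") %in% groups_present))
      cons <- c(cons, list(c("gradeI", "gradeII")))
  } else if (length(groups_present) >= 2) {
    cons <- list(groups_present[1:2])
  }
  cons
}

compare_one <- function(va, vb, measure, ga, gb, with_fold, alpha_grid) {
  if (!length(va) || !length(vb)) {
    return(data.frame(measure = measure, group_a = ga, group_b = gb,
                      n_a = length(va), n_b = length(vb),
                      u = NA_real_, z = NA_real_, p = NA_real_,
                      fold_change = NA_real_,
                      median_a = if (length(va)) median(va) else NA_real_,
                      median_b = if (length(vb)) median(vb) else NA_real_,
                      median_diff = NA_real_, significant_at = NA_real_,
                      note = "no data"))
  }
  mw <- mann_whitney_u(va, vb)
  fold <- if (with_fold && mean(va) > 0)
    fold_change(va, vb) else NA_real_
  data.frame(measure = measure, group_a = ga, group_b = gb,
             n_a = length(va), n_b = length(vb),
             u = mw$u, z = mw$z, p = mw$p,
             fold_change = fold,
             median_a = median(va), median_b = median(vb),
             median_diff = median(vb) - median(va),
             significant_at = significant_at(mw$p, alpha_grid),
             note = if (length(va) < 2 || length(vb) < 2) "low n" else "")
}

#' Group contrasts of per-core channel intensities
#'
#' For each channel and each contrast, compares the per-core `mean_gray`
#' values of the two groups with the Mann-Whitney U test and reports the
#' fold change of group means (group b over group a, a being the
#' reference/control side).
#'
#' @param quant_table Output of [batch_quantify()] (columns `core_id, group,
#'   channel` plus the measure column).
#' @param contrasts List of 2-vectors of group labels; the pooled label
#'   `"malignant"` means all tumor-grade groups present. `NULL` selects the
#'   default set: control vs malignant, control vs each grade, grade I vs
#'   grade II.
#' @param measure Column of `quant_table` to compare (default `"mean_gray"`).
#' @param alpha_grid Significance grid reported in `significant_at`.
#' @return A `group_comparison` data.frame, one row per channel x contrast.
#' @export
compare_intensities <- function(quant_table, contrasts = NULL,
                                measure = "mean_gray",
                                alpha_grid = alpha_grid_default) {
  stopifnot(is.data.frame(quant_table), measure %in% names(quant_table))
  groups_present <- unique(quant_table$group)
  if (is.null(contrasts)) contrasts <- default_contrasts(groups_present)
  if (!length(contrasts)) stop("no contrasts to evaluate")
  rows <- list()
  for (ch in intersect(tma_channels(), unique(quant_table$channel))) {
    sub <- quant_table[quant_table$channel == ch & !is.na(quant_table[[measure]]), ]
    for (con in contrasts) {
      ga <- resolve_groups(con[1], groups_present)
      gb <- resolve_groups(con[2], groups_present)
      va <- sub[[measure]][sub$group %in% ga]
      vb <- sub[[measure]][sub$group %in% gb]
      if (!length(va) || !length(vb))
        warning("contrast ", con[1], " vs ", con[2], " has no segmented ",
                "cores on one side for ", ch, "; reported as NA",
                call. = FALSE)
      rows[[length(rows) + 1L]] <-
        compare_one(va, vb, paste(ch, measure), con[1], con[2],
                    with_fold = TRUE, alpha_grid = alpha_grid)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "n_comparisons") <- nrow(out)
  out
}

#' Group contrasts of per-ROI co-localization coefficients
#'
#' As [compare_intensities()], but the sampling unit is the per-ROI Pearson
#' coefficient of a channel pair; no fold change is reported (a correlation
#' has no meaningful ratio scale) — the median difference is used instead.
#'
#' @param coloc_table Output of [coloc_cohort()].
#' @param contrasts As in [compare_intensities()].
#' @param alpha_grid Significance grid.
#' @return A `group_comparison` data.frame, one row per channel pair x
#'   contrast.
#' @export
compare_coloc <- function(coloc_table, contrasts = NULL,
                          alpha_grid = alpha_grid_default) {
  stopifnot(is.data.frame(coloc_table))
  groups_present <- unique(coloc_table$group)
  if (is.null(contrasts)) {
    contrasts <- Filter(function(con) !"malignant" %in% con,
                        default_contrasts(groups_present))
  }
  if (!length(contrasts)) stop("no contrasts to evaluate")
  pairs <- channel_pairs()
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    sub <- coloc_table[coloc_table$channel_a == pairs[p, 1] &
                       coloc_table$channel_b == pairs[p, 2] &
                       !is.na(coloc_table$pearson_r), ]
    for (con in contrasts) {
      ga <- resolve_groups(con[1], groups_present)
      gb <- resolve_groups(con[2], groups_present)
      va <- sub$pearson_r[sub$group %in% ga]
      vb <- sub$pearson_r[sub$group %in% gb]
      rows[[length(rows) + 1L]] <-
        compare_one(va, vb, paste0(pairs[p, 1], ":", pairs[p, 2], " pearson_r"),
                    con[1], con[2], with_fold = FALSE, alpha_grid = alpha_grid)
    }
  }
  if (!length(rows)) stop("no channel pair had data for any contrast")
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "n_comparisons") <- nrow(out)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", nrow(x), "contrasts",
      "(no multiplicity correction applied)\n")
  show <- x
  show$p <- signif(show$p, 3)
  show$z <- round(show$z, 2)
  show$median_a <- signif(show$median_a, 4)
  show$median_b <- signif(show$median_b, 4)
  show$median_diff <- signif(show$median_diff, 4)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Box-plot summary statistics
#'
#' Median, quartiles, 99th percentile and extremes of a sample, matching the
#' published box plots (filled circle = 99% value, line = median). Quantiles
#' use linear interpolation between order statistics.
#'
#' @param values Nonempty numeric vector.
#' @return Named list: `median, q1, q3, p99, min, max, n`.
#' @export
#' @examples
#' summarize_box(1:100)  # median 50.5, p99 = 99.01
summarize_box <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  q <- quantile(values, c(0.25, 0.5, 0.75, 0.99), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], p99 = q[4],
       min = min(values), max = max(values), n = length(values))
}
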