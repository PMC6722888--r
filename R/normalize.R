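#' Percentile-clipped z-score normalization of marker intensities
#'
#' For each requested channel, pooled over all rows of the table: values
#' above the `clip_percentile`-th percentile are set to that percentile
#' (hot-pixel robustness), then standardized as `z = (x - mean) / sd`
#' with the sample standard deviation. Constant columns map to all-zero
#' z-scores. Clipping happens before standardization; set
#' `clip_percentile = 100` to disable it.
#'
#' @param table A cell table.
#' @param channels Marker names (`mean_<marker>` columns) and/or literal
#'   column names (e.g. `area_um2`) to standardize. Defaults to all
#'   `mean_*` columns plus the size parameters.
#' @param clip_percentile Upper percentile used as clipping cutoff
#'   (default 99).
#' @return The table with one added `z_<name>` column per input column
#'   (`z_<marker>` for intensity columns).
#' @export
zscore_cells <- function(table, channels = NULL, clip_percentile = 99) {
  abort_if(nrow(table) == 0, "cannot z-score an empty table")
  abort_if(nrow(table) < 2, "z-scoring needs at least 2 cells")
  if (is.null(channels)) {
    cols <- c(intensity_columns(table),
              intersect(size_columns(), names(table)))
  } else {
    cols <- ifelse(paste0("mean_", channels) %in% names(table),
                   paste0("mean_", channels), channels)
  }
  missing <- setdiff(cols, names(table))
  abort_if(length(missing) > 0, "columns not in table: %s",
           paste(missing, collapse = ", "))
  for (col in cols) {
    x <- clip_upper_percentile(table[[col]], clip_percentile)
    s <- stats::sd(x)
    z <- if (is.na(s) || s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
    table[[paste0("z_", sub("^mean_", "", col))]] <- z
  }
  table
}

#' Mann-Whitney (Wilcoxon rank-sum) test with a two-tailed P value
#'
#' U is computed from rank sums with midranks for ties. The P value is
#' exact (by enumeration over rank assignments) when the pooled sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used. Set `exact`
#' to force either path.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact `NULL` (auto), `TRUE`, or `FALSE`.
#' @return A tibble with columns `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  abort_if(length(a) == 0 || length(b) == 0,
           "both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- (length(a) + length(b) <= 12) && !ties
  if (exact && ties) exact <- FALSE   # exact distribution assumes no ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal")
}

#' Per-channel condition comparison statistics
#'
#' For each channel and each non-reference condition versus each
#' reference condition: group means, standard errors of the mean, the
#' Mann-Whitney U statistic (or Welch t, see `method`), the two-tailed P
#' value, and a significance flag at P < 0.05. P values are reported raw,
#' without multiple-testing correction.
#'
#' @param table A cell table with a `condition` column.
#' @param channels Columns to compare (marker names or literal column
#'   names, as in [zscore_cells()]).
#' @param reference_conditions Conditions each remaining condition is
#'   tested against.
#' @param method `"mann_whitney"` (default) or `"t_test"` (unpaired,
#'   Welch).
#' @return A tibble of class `condition_stats` with one row per
#'   (channel, condition, reference) triple.
#' @export
compare_conditions <- function(table, channels,
                               reference_conditions = c("nontreated",
                                                        "DMSO"),
                               method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  conds <- unique(table$condition)
  abort_if(length(conds) < 2, "need at least 2 conditions")
  missing <- setdiff(reference_conditions, conds)
  abort_if(length(missing) > 0, "unknown reference condition: %s",
           paste(missing, collapse = ", "))
  cols <- ifelse(paste0("mean_", channels) %in% names(table),
                 paste0("mean_", channels),
                 ifelse(paste0("z_", channels) %in% names(table),
                        paste0("z_", channels), channels))
  bad <- setdiff(cols, names(table))
  abort_if(length(bad) > 0, "columns not in table: %s",
           paste(bad, collapse = ", "))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- list()
  for (col in cols) {
    for (ref in reference_conditions) {
      xr <- table[[col]][table$condition == ref]
      for (cond in setdiff(conds, ref)) {
        xc <- table[[col]][table$condition == cond]
        if (method == "mann_whitney") {
          ht <- mann_whitney(xc, xr)
          stat <- ht$U; p <- ht$p_value
        } else {
          tt <- stats::t.test(xc, xr)
          stat <- unname(tt$statistic); p <- tt$p.value
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = col, condition = cond, reference = ref,
          n = length(xc), n_ref = length(xr),
          mean = mean(xc), mean_ref = mean(xr),
          sem = sem(xc), sem_ref = sem(xr),
          statistic = stat, p_value = p, significant = p < 0.05)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("condition_stats", class(out))
  out
}

#' Paint per-cell z-scores back onto the image plane
#'
#' Produces an H x W real image in which every pixel of a cell carries
#' that cell's value of `channel_z` and background pixels carry `NA` (the
#' reserved sentinel). Rendering via [ggplot2::autoplot()] uses a fixed
#' symmetric color scale so maps from different ROIs are directly
#' comparable.
#'
#' @param mask Cell [label_mask()].
#' @param table Cell table containing `cell_id` and the `channel_z`
#'   column; every mask label must be present.
#' @param channel_z Column to paint (typically a `z_*` column).
#' @return An H x W matrix of class `spatial_heatmap` with attributes
#'   `channel` and `zlim`.
#' @export
spatial_heatmap <- function(mask, table, channel_z) {
  abort_if(!channel_z %in% names(table), "column '%s' not in table",
           channel_z)
  labs <- mask_labels(mask)
  missing <- setdiff(labs, table$cell_id)
  abort_if(length(missing) > 0,
           "table is missing mask labels: %s",
           paste(utils::head(missing, 10), collapse = ", "))
  img <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (length(labs) > 0) {
    idx <- which(unclass(mask) > 0L)
    img[idx] <- table[[channel_z]][match(mask[idx], table$cell_id)]
  }
  structure(img, channel = channel_z,
            zlim = c(-1, 1) * max(abs(img), 1e-9, na.rm = TRUE),
            class = "spatial_heatmap")
}
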