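#' Extract per-cell morphology and mean marker intensities
#'
#' For every labeled cell: the mean of each channel over the whole-cell
#' mask, area (pixel count times pixel area), perimeter (boundary contour
#' length), major/minor axis lengths and eccentricity of the second-moment
#' ellipse, and the unweighted pixel centroid. Intensities are measured
#' over the whole-cell mask for all channels, matching a single exported
#' mean intensity per marker per cell. Lengths are reported in
#' micrometres, areas in um^2; coordinates are pixel-centered with origin
#' at the image's top-left corner.
#'
#' @param stack An [imc_stack()].
#' @param cells Whole-cell [label_mask()].
#' @param nuclei Optional nuclei [label_mask()]; when supplied its label
#'   set must equal the cell mask's.
#' @param condition Condition label stored in the output (defaults to the
#'   stack's).
#' @return A tibble with one row per cell, sorted by `cell_id`: identifier
#'   and condition columns, `centroid_x_um`, `centroid_y_um`, `area_um2`,
#'   `perimeter_um`, `major_axis_um`, `minor_axis_um`, `eccentricity`, and
#'   one `mean_<marker>` column per panel channel.
#' @export
extract_features <- function(stack, cells, nuclei = NULL, condition = NULL) {
  d <- dim(stack$pixels)
  abort_if(nrow(cells) != d[1] || ncol(cells) != d[2],
           "cell mask shape (%d x %d) does not match stack (%d x %d)",
           nrow(cells), ncol(cells), d[1], d[2])
  if (!is.null(nuclei)) {
    abort_if(nrow(nuclei) != d[1] || ncol(nuclei) != d[2],
             "nuclei mask shape does not match stack")
    abort_if(!identical(mask_labels(nuclei), mask_labels(cells)),
             "label sets of cell and nuclei masks differ")
  }
  ps <- stack$pixel_size
  labs <- mask_labels(cells)
  if (length(labs) == 0) {
    out <- tibble::tibble(cell_id = integer(0), roi_id = character(0),
                          condition = character(0),
                          centroid_x_um = numeric(0),
                          centroid_y_um = numeric(0), area_um2 = numeric(0),
                          perimeter_um = numeric(0),
                          major_axis_um = numeric(0),
                          minor_axis_um = numeric(0),
                          eccentricity = numeric(0))
    for (mk in stack$panel$marker) out[[paste0("mean_", mk)]] <- numeric(0)
    return(out)
  }
  idx <- which(cells > 0L)
  lab_at <- as.integer(cells[idx])
  f <- factor(lab_at, levels = labs)
  npx <- as.integer(table(f))
  ri <- (idx - 1L) %% d[1] + 1L
  ci <- (idx - 1L) %/% d[1] + 1L
  cx <- rowsum((ci - 1) * ps, f)[, 1] / npx
  cy <- rowsum((ri - 1) * ps, f)[, 1] / npx

  # shape features from EBImage on a consecutively relabeled mask
  dense <- matrix(0L, d[1], d[2])
  dense[idx] <- match(lab_at, labs)
  sh <- EBImage::computeFeatures.shape(dense)
  mo <- EBImage::computeFeatures.moment(dense)
  perim <- sh[, "s.perimeter"] * ps
  major <- mo[, "m.majoraxis"] * ps
  ecc <- mo[, "m.eccentricity"]
  minor <- major * sqrt(pmax(0, 1 - ecc^2))

  cond <- condition %||% stack$condition
  out <- tibble::tibble(
    cell_id = labs, roi_id = stack$roi_id,
    condition = as.character(cond),
    centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy),
    area_um2 = npx * ps^2, perimeter_um = as.numeric(perim),
    major_axis_um = as.numeric(major), minor_axis_um = as.numeric(minor),
    eccentricity = as.numeric(ecc))
  for (k in seq_len(d[3])) {
    vals <- stack$pixels[, , k][idx]
    out[[paste0("mean_", stack$panel$marker[k])]] <-
      as.numeric(rowsum(vals, f)[, 1] / npx)
  }
  dplyr::arrange(out, .data$cell_id)
}

#' Marker mean-intensity column names of a cell table
#'
#' @param table A cell table.
#' @return Character vector of `mean_*` column names.
#' @export
intensity_columns <- function(table) {
  grep("^mean_", names(table), value = TRUE)
}

#' Cell size parameter column names
#' @return The four morphology columns used alongside marker intensities.
#' @export
size_columns <- function() {
  c("area_um2", "perimeter_um", "major_axis_um", "minor_axis_um")
}
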