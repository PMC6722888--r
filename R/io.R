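# On-disk artifacts. Stacks are multipage grayscale TIFFs, one page per
# channel in panel order; a sidecar panel CSV (<path>.panel.csv) and a
# sidecar metadata JSON (<path>.meta.json) carry channel names, pixel
# size, identifiers, and the intensity scale used to place values into
# the TIFF's [0, 1] sample range. Label masks are single-page unsigned
# 16-bit TIFFs. Cell tables are plain CSV.

stack_sidecar_panel <- function(path) paste0(path, ".panel.csv")
stack_sidecar_meta <- function(path) paste0(path, ".meta.json")

#' Write / read a multichannel image stack as a multipage TIFF
#'
#' 16-bit files store rounded integer counts (values must not exceed
#' 65535; overflow is an error, never a silent clip) and round-trip
#' bit-exactly. 32-bit files store IEEE floats scaled by a recorded
#' constant and round-trip to 32-bit float precision.
#'
#' @param stack An [imc_stack()].
#' @param path Output TIFF path; sidecar files `<path>.panel.csv` and
#'   `<path>.meta.json` are written alongside.
#' @param bit_depth 16 or 32.
#' @return `write_stack()` returns `path` invisibly; `read_stack()`
#'   returns an [imc_stack()].
#' @export
write_stack <- function(stack, path, bit_depth = 16) {
  abort_if(!bit_depth %in% c(16, 32), "bit_depth must be 16 or 32")
  px <- stack$pixels
  if (bit_depth == 16) {
    abort_if(max(round(px)) > 65535,
             "value %g overflows 16-bit storage; use bit_depth = 32",
             max(px))
    scale <- 65535
    pages <- lapply(seq_len(dim(px)[3]),
                    function(k) round(px[, , k]) / scale)
  } else {
    scale <- max(65535, 2^ceiling(log2(max(px, 1))))
    pages <- lapply(seq_len(dim(px)[3]), function(k) px[, , k] / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "LZW", reduce = FALSE)
  write_panel(stack$panel, stack_sidecar_panel(path))
  jsonlite::write_json(
    list(roi_id = stack$roi_id, condition = stack$condition,
         pixel_size = stack$pixel_size, bit_depth = bit_depth,
         scale = scale),
    stack_sidecar_meta(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param panel_path Optional explicit panel CSV (used when no sidecar
#'   panel exists). With neither, channels are auto-named `ch00..chNN`
#'   with compartment `"any"`.
#' @export
read_stack <- function(path, panel_path = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(stack_sidecar_meta(path))) {
    meta <- jsonlite::read_json(stack_sidecar_meta(path),
                                simplifyVector = TRUE)
  }
  scale <- meta$scale %||% 65535
  bits <- attr(pages[[1]], "bits.per.sample") %||% meta$bit_depth %||% 16
  panel <- NULL
  if (!is.null(panel_path)) {
    panel <- read_panel(panel_path)
  } else if (file.exists(stack_sidecar_panel(path))) {
    panel <- read_panel(stack_sidecar_panel(path))
  }
  C <- length(pages)
  if (is.null(panel)) {
    panel <- imc_panel(metal_tag = sprintf("ch%02d", seq_len(C) - 1),
                       marker = sprintf("ch%02d", seq_len(C) - 1),
                       compartment = rep("any", C))
  }
  abort_if(nrow(panel) != C,
           "stack has %d pages but panel has %d channels", C, nrow(panel))
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  px <- array(0, dim = c(H, W, C))
  for (k in seq_len(C)) {
    v <- pages[[k]] * scale
    if (bits == 16) v <- round(v)
    px[, , k] <- v
  }
  imc_stack(px, panel, pixel_size = meta$pixel_size %||% 1,
            roi_id = meta$roi_id %||% sub("\\.tiff?$", "", basename(path)),
            condition = meta$condition %||% NA_character_)
}

#' Write / read a label mask as an unsigned 16-bit TIFF
#'
#' @param mask A [label_mask()]; labels must not exceed 65535.
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns
#'   a [label_mask()].
#' @export
write_mask <- function(mask, path) {
  abort_if(max(mask) > 65535L,
           "mask labels exceed 65535 and cannot be stored as 16-bit")
  tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16,
                  compression = "LZW", reduce = FALSE)
  jsonlite::write_json(list(kind = attr(mask, "kind")),
                       stack_sidecar_meta(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @param kind Object kind when no sidecar records it.
#' @export
read_mask <- function(path, kind = NULL) {
  m <- round(tiff::readTIFF(path) * 65535)
  if (is.null(kind) && file.exists(stack_sidecar_meta(path))) {
    kind <- jsonlite::read_json(stack_sidecar_meta(path))$kind
  }
  label_mask(matrix(as.integer(m), nrow(m), ncol(m)),
             kind = kind %||% "cells")
}

#' Write / read a per-cell measurement table as CSV
#'
#' Column layout: identifiers (`cell_id`, `roi_id`, `condition`), centroid
#' and morphology columns, one `mean_<marker>` column per channel, and
#' optional `true_class` / `pred_class` columns. Unknown columns are
#' preserved verbatim. Numeric values round-trip to at least 1e-9
#' relative precision.
#'
#' @param table A cell table (tibble).
#' @param path CSV path.
#' @return `write_cell_table()` returns `path` invisibly;
#'   `read_cell_table()` returns a tibble.
#' @export
write_cell_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a synthetic ROI to a directory
#'
#' Writes the stack (16-bit multipage TIFF + sidecars), both truth masks,
#' and the truth table of one [render_roi()] result.
#'
#' @param roi A `synthetic_roi`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic_roi <- function(roi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- roi$stack$roi_id
  write_stack(roi$stack, file.path(dir, paste0(id, "_stack.tiff")))
  write_mask(roi$truth_nuclei, file.path(dir, paste0(id, "_nuclei.tiff")))
  write_mask(roi$truth_cells, file.path(dir, paste0(id, "_cells.tiff")))
  write_cell_table(roi$truth_table, file.path(dir, paste0(id, "_truth.csv")))
  invisible(dir)
}
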