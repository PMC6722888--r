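#' Construct a multichannel ROI image stack
#'
#' An `imc_stack` bundles an H x W x C array of nonnegative ion counts with
#' its channel panel, pixel size, and ROI/condition identifiers. Channel
#' `k` of the array corresponds to row `k` of the panel.
#'
#' @param pixels Numeric H x W x C array (an H x W matrix is promoted to a
#'   single-channel array). All values must be nonnegative and finite.
#' @param panel An [imc_panel()] with C rows.
#' @param pixel_size Pixel edge length in micrometres (default 1).
#' @param roi_id,condition Identifier strings carried into cell tables.
#' @return An object of class `imc_stack`.
#' @export
imc_stack <- function(pixels, panel, pixel_size = 1, roi_id = "roi",
                      condition = NA_character_) {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  abort_if(length(dim(pixels)) != 3L, "pixels must be an H x W x C array")
  abort_if(dim(pixels)[3] != nrow(panel),
           "stack has %d channels but panel has %d rows",
           dim(pixels)[3], nrow(panel))
  abort_if(anyNA(pixels) || min(pixels) < 0,
           "pixel values must be nonnegative and non-missing")
  abort_if(pixel_size <= 0, "pixel_size must be positive")
  structure(list(pixels = pixels, panel = panel,
                 pixel_size = as.numeric(pixel_size),
                 roi_id = as.character(roi_id),
                 condition = as.character(condition)),
            class = "imc_stack")
}

#' @export
print.imc_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<imc_stack> %s (%s): %d x %d px, %d channels, %g um/px\n",
              x$roi_id, x$condition, d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.imc_stack <- function(x) dim(x$pixels)

#' Extract one channel of a stack as a matrix
#'
#' @param stack An [imc_stack()].
#' @param marker Marker name (a row of the panel).
#' @return H x W numeric matrix.
#' @export
get_channel <- function(stack, marker) {
  i <- match(marker, stack$panel$marker)
  abort_if(is.na(i), "channel '%s' is not in the panel", marker)
  stack$pixels[, , i]
}

#' Construct a label mask
#'
#' A label mask is an H x W integer image: 0 marks background and each
#' positive value `k` marks the pixels of object `k`. The same container is
#' used for primary objects (nuclei) and secondary objects (whole cells).
#'
#' @param labels Integer-valued H x W matrix, all values >= 0.
#' @param kind `"nuclei"` or `"cells"`.
#' @return An integer matrix of class `label_mask` with a `kind` attribute.
#' @export
label_mask <- function(labels, kind = c("nuclei", "cells")) {
  kind <- match.arg(kind)
  abort_if(!is.matrix(labels), "labels must be a matrix")
  abort_if(anyNA(labels) || min(labels) < 0,
           "labels must be nonnegative and non-missing")
  abort_if(max(abs(labels - round(labels))) > 0, "labels must be integers")
  storage.mode(labels) <- "integer"
  structure(labels, kind = kind, class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask:%s> %d x %d px, %d objects\n", attr(x, "kind"),
              nrow(x), ncol(x), length(mask_labels(x))))
  invisible(x)
}

#' Sorted vector of object labels present in a mask (excluding background)
#' @param mask A [label_mask()].
#' @export
mask_labels <- function(mask) sort(unique(mask[mask > 0L]))
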