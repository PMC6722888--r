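#' Segmentation parameters
#'
#' Settings for the two-stage primary/secondary object strategy: nuclei
#' are found on the DNA-intercalator channel, whole cells grow out from
#' the nuclei over a cytoplasmic-marker foreground.
#'
#' @param nuclear_channel Marker used for primary objects (nuclei).
#' @param cyto_channel Marker used for the secondary-object foreground.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_diameter,max_diameter Equivalent-diameter bounds (pixels)
#'   for accepted nuclei; also sets the declumping suppression radius.
#' @param declump Split touching nuclei by distance-transform watershed.
#' @param cyto_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Count threshold when `cyto_threshold_method` is
#'   `"fixed"` (applied to raw counts).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(nuclear_channel = "Ir191-DNA",
                                cyto_channel = "pan-keratin",
                                smooth_sigma = 1, min_diameter = 6,
                                max_diameter = 30, declump = TRUE,
                                cyto_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL) {
  cyto_threshold_method <- match.arg(cyto_threshold_method)
  abort_if(smooth_sigma < 0, "smooth_sigma must be >= 0")
  abort_if(min_diameter <= 0 || min_diameter >= max_diameter,
           "need 0 < min_diameter < max_diameter")
  abort_if(cyto_threshold_method == "fixed" && is.null(fixed_threshold),
           "fixed_threshold required for cyto_threshold_method = 'fixed'")
  structure(list(nuclear_channel = nuclear_channel,
                 cyto_channel = cyto_channel, smooth_sigma = smooth_sigma,
                 min_diameter = min_diameter, max_diameter = max_diameter,
                 declump = declump,
                 cyto_threshold_method = cyto_threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "segmentation_params")
}

# Otsu threshold of a smoothed log1p count image; returns logical matrix.
# Degenerate (near-constant) images yield an all-FALSE foreground.
.threshold_foreground <- function(img, sigma) {
  x <- log1p(img)
  if (sigma > 0) x <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma))
  mx <- max(x)
  if (mx <= 0 || stats::sd(x) < 1e-8) {
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  thr <- EBImage::otsu(EBImage::Image(x / mx), range = c(0, 1)) * mx
  x > thr
}

#' Segment nuclei from the DNA-intercalator channel
#'
#' Gaussian-smooths log1p counts, applies a global Otsu threshold, fills
#' holes, optionally splits touching nuclei by watershed on the Euclidean
#' distance transform, and removes objects outside the configured
#' equivalent-diameter range. Fully deterministic.
#'
#' @param stack An [imc_stack()].
#' @param params A [segmentation_params()].
#' @return A nuclei [label_mask()] with consecutive labels `1..K`; a blank
#'   image yields an empty mask.
#' @export
segment_nuclei <- function(stack, params = segmentation_params()) {
  img <- get_channel(stack, params$nuclear_channel)
  fg <- .threshold_foreground(img, params$smooth_sigma)
  if (!any(fg)) {
    return(label_mask(matrix(0L, nrow(img), ncol(img)), "nuclei"))
  }
  mask <- EBImage::fillHull(EBImage::Image(fg * 1))
  if (params$declump) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1,
                              ext = max(1L, round(params$min_diameter / 2)))
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  # equivalent-diameter size filter, then consecutive relabeling
  sizes <- tabulate(lab[lab > 0])
  ed <- 2 * sqrt(sizes / pi)
  ok <- which(ed >= params$min_diameter & ed <= params$max_diameter)
  remap <- integer(length(sizes))
  remap[ok] <- seq_along(ok)
  pos <- lab > 0
  lab[pos] <- remap[lab[pos]]
  label_mask(matrix(as.integer(lab), nrow(lab), ncol(lab)), "nuclei")
}

#' Grow whole-cell objects from segmented nuclei
#'
#' The foreground is the union of the Otsu-thresholded (or fixed-
#' thresholded) smoothed cytoplasmic channel and the nuclei pixels; each
#' foreground pixel is then assigned to a nucleus by seeded region growing
#' on the smoothed cytoplasmic intensity (Voronoi propagation on an
#' intensity-weighted metric). Cells inherit their nucleus label, every
#' nucleus pixel belongs to its own cell, and no label absent from the
#' nuclei mask can appear.
#'
#' @param stack An [imc_stack()].
#' @param nuclei Nuclei [label_mask()] from [segment_nuclei()].
#' @param params A [segmentation_params()].
#' @return A cell [label_mask()] whose label set equals the nuclei mask's.
#' @export
segment_cells <- function(stack, nuclei, params = segmentation_params()) {
  d <- dim(stack$pixels)
  abort_if(nrow(nuclei) != d[1] || ncol(nuclei) != d[2],
           "nuclei mask shape (%d x %d) does not match stack (%d x %d)",
           nrow(nuclei), ncol(nuclei), d[1], d[2])
  if (max(nuclei) == 0L) {
    return(label_mask(matrix(0L, d[1], d[2]), "cells"))
  }
  img <- get_channel(stack, params$cyto_channel)
  x <- log1p(img)
  if (params$smooth_sigma > 0) {
    x <- as.matrix(EBImage::gblur(EBImage::Image(x), params$smooth_sigma))
  }
  if (params$cyto_threshold_method == "fixed") {
    fg <- img > params$fixed_threshold
  } else {
    fg <- .threshold_foreground(img, params$smooth_sigma)
  }
  fg <- fg | (unclass(nuclei) > 0L)
  lab <- EBImage::propagate(EBImage::Image(x),
                            seeds = EBImage::Image(unclass(nuclei)),
                            mask = EBImage::Image(fg), lambda = 1e-4)
  lab <- as.matrix(EBImage::imageData(lab))
  label_mask(matrix(as.integer(lab), nrow(lab), ncol(lab)), "cells")
}

#' Pixel-level segmentation precision and recall against a reference
#'
#' Both masks are binarized (any label > 0 is foreground) and overlapped:
#' precision = TP / (TP + FP), recall = TP / (TP + FN) over pixels. An
#' empty test mask has precision 1 when the truth is also empty, else 0.
#'
#' @param test Predicted [label_mask()].
#' @param truth Ground-truth [label_mask()] of the same shape.
#' @return A tibble with columns `precision` and `recall`.
#' @export
overlap_precision <- function(test, truth) {
  abort_if(!all(dim(test) == dim(truth)),
           "mask shapes differ: %d x %d vs %d x %d",
           nrow(test), ncol(test), nrow(truth), ncol(truth))
  a <- unclass(test) > 0L
  b <- unclass(truth) > 0L
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  tibble::tibble(precision = precision, recall = recall)
}
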