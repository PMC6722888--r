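#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spatial z-score heatmap
#'
#' Renders a [spatial_heatmap()] image with a symmetric diverging color
#' scale. Passing a shared `zlim` (e.g. the largest |z| over a set of
#' ROIs) puts several ROIs on one comparable scale.
#'
#' @param object A `spatial_heatmap`.
#' @param zlim Symmetric color limits; defaults to the matrix's own.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spatial_heatmap <- function(object, zlim = NULL, ...) {
  zlim <- zlim %||% attr(object, "zlim")
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$z <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = zlim, na.value = "grey15",
                                  name = attr(object, "channel")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a normalized confusion matrix
#'
#' @param object A `confusion_matrix` from [cross_validate()].
#' @param ... Ignored.
#' @return A ggplot object on a 0-1 fill scale.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  df$true <- factor(df$true, rev(rownames(object)))
  df$pred <- factor(df$pred, colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$fraction)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot a Pearson similarity heatmap in dendrogram order
#'
#' Rows and columns follow the complete-linkage leaf order from
#' [hierarchical_order()]; color limits are fixed to [-1, 1] so heatmaps
#' from different populations are comparable.
#'
#' @param object A `similarity_matrix`.
#' @param order Optional `param_dendrogram`; computed when absent and the
#'   matrix is complete.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, order = NULL, ...) {
  m <- unclass(object)
  if (is.null(order) && !anyNA(m)) order <- hierarchical_order(object)
  lv <- if (is.null(order)) rownames(m) else order$labels
  df <- tibble::tibble(
    a = factor(rep(rownames(m), times = ncol(m)), lv),
    b = factor(rep(colnames(m), each = nrow(m)), lv),
    r = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey80",
                                  name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Per-condition marker summary plot (mean with SEM error bars)
#'
#' @param stats A `condition_stats` table from [compare_conditions()].
#' @param ... Ignored.
#' @return A ggplot object faceted by channel.
#' @export
autoplot.condition_stats <- function(object, ...) {
  stats <- object
  df <- dplyr::distinct(stats, .data$channel, .data$condition,
                        .data$mean, .data$sem)
  refs <- dplyr::distinct(stats, .data$channel,
                          condition = .data$reference,
                          mean = .data$mean_ref, sem = .data$sem_ref)
  df <- dplyr::bind_rows(df, refs) |> dplyr::distinct()
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = "mean +/- SEM")
}
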