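#' t-SNE embedding of single-cell features
#'
#' Embeds cells in two dimensions from z-scored marker and size features.
#' Feature columns are put into canonical (alphabetical) order before
#' embedding, so the result is invariant to the column order of the input
#' table; initialization uses the first two principal components, and the
#' whole computation is deterministic given `seed`.
#'
#' @param table A cell table that already carries the feature columns
#'   (typically from [zscore_cells()]).
#' @param feature_names Columns to embed; defaults to all `z_*` columns.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `nrow(table) - 1 >= 3 * perplexity`.
#' @param max_iter Gradient-descent iterations.
#' @return A tibble of class `tsne_embedding` with columns `cell_id`,
#'   `condition` (if present), `tsne1`, `tsne2`, and attributes
#'   `feature_names`, `seed`, `perplexity`.
#' @export
tsne_embed <- function(table, feature_names = NULL, seed = 42,
                       perplexity = 30, max_iter = 500) {
  if (is.null(feature_names)) {
    feature_names <- grep("^z_", names(table), value = TRUE)
  }
  abort_if(length(feature_names) == 0, "no feature columns to embed")
  missing <- setdiff(feature_names, names(table))
  abort_if(length(missing) > 0, "feature columns not in table: %s",
           paste(missing, collapse = ", "))
  n <- nrow(table)
  abort_if(n - 1 < 3 * perplexity,
           "perplexity %g needs more than %d cells (have %d)",
           perplexity, ceiling(3 * perplexity + 1), n)
  feats <- sort(feature_names)
  X <- as.matrix(table[, feats])
  init <- stats::prcomp(X, rank. = 2, center = TRUE, scale. = FALSE)$x
  init <- init / max(stats::sd(init[, 1]), 1e-12) * 1e-4
  fit <- withr::with_seed(seed, Rtsne::Rtsne(
    X, dims = 2, perplexity = perplexity, theta = 0.5, pca = FALSE,
    max_iter = max_iter, Y_init = init, check_duplicates = FALSE,
    verbose = FALSE))
  out <- tibble::tibble(
    cell_id = if ("cell_id" %in% names(table)) table$cell_id else seq_len(n),
    tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  if ("roi_id" %in% names(table)) out$roi_id <- table$roi_id
  if ("condition" %in% names(table)) out$condition <- table$condition
  attr(out, "feature_names") <- feats
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  class(out) <- c("tsne_embedding", class(out))
  out
}

#' Condition colors matching the published palette roles
#'
#' EGF green, etoposide black, nocodazole purple, DMSO red, nontreated
#' blue.
#' @return Named character vector of colors.
#' @export
condition_palette <- function() {
  c(nontreated = "#2166ac", DMSO = "#d6604d", EGF = "#1a9850",
    etoposide = "#1a1a1a", nocodazole = "#762a83")
}

#' @rdname tsne_embed
#' @param object A `tsne_embedding`.
#' @param colour Column to color points by: `"condition"` (default) or
#'   any feature column of `table`.
#' @param table Optional cell table supplying feature columns for
#'   coloring.
#' @param ... Ignored.
#' @export
autoplot.tsne_embedding <- function(object, colour = "condition",
                                    table = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!colour %in% names(df) && !is.null(table)) {
    df[[colour]] <- table[[colour]]
  }
  abort_if(!colour %in% names(df), "color column '%s' not available",
           colour)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2,
                                        colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (identical(colour, "condition")) {
    pal <- condition_palette()
    known <- intersect(unique(df$condition), names(pal))
    if (length(known) == length(unique(df$condition))) {
      p <- p + ggplot2::scale_colour_manual(values = pal)
    }
  } else if (is.numeric(df[[colour]])) {
    p <- p + ggplot2::scale_colour_viridis_c()
  }
  p
}
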