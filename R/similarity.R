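#' Pairwise Pearson similarity of measured parameters over a cell
#' population
#'
#' Correlates raw (non-normalized) parameter columns across the cells of
#' a classified population. Constant columns yield undefined correlations
#' which are kept as `NA`, never coerced to 0; the diagonal is exactly 1.
#'
#' @param table A cell table.
#' @param parameters Columns to correlate (marker names are resolved to
#'   their `mean_*` columns).
#' @param population Optional class label; rows are filtered to
#'   `pred_class == population` (falling back to `true_class` when no
#'   predictions are present).
#' @return A P x P matrix of class `similarity_matrix` with attribute
#'   `n_cells`.
#' @export
pearson_matrix <- function(table, parameters, population = NULL) {
  if (!is.null(population)) {
    cls_col <- if ("pred_class" %in% names(table)) "pred_class"
               else "true_class"
    abort_if(!cls_col %in% names(table),
             "no pred_class/true_class column to filter population on")
    table <- table[table[[cls_col]] == population, ]
  }
  cols <- ifelse(paste0("mean_", parameters) %in% names(table),
                 paste0("mean_", parameters), parameters)
  missing <- setdiff(cols, names(table))
  abort_if(length(missing) > 0, "columns not in table: %s",
           paste(missing, collapse = ", "))
  abort_if(nrow(table) < 3,
           "need at least 3 cells after filtering (have %d)", nrow(table))
  X <- as.matrix(table[, cols])
  r <- suppressWarnings(stats::cor(X, method = "pearson"))
  diag(r) <- 1
  dimnames(r) <- list(parameters, parameters)
  structure(r, n_cells = nrow(table), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d parameters over %d cells\n",
              nrow(x), attr(x, "n_cells") %||% NA))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Complete-linkage ordering of parameters by Pearson distance
#'
#' Agglomerates parameters with distance `1 - r` and the complete linkage
#' method; deterministic, with merge ties resolved by the input parameter
#' order.
#'
#' @param sim A [pearson_matrix()] result without missing entries.
#' @return A list of class `param_dendrogram`: `labels` (leaf order),
#'   `order` (leaf indices), the underlying `hclust` object, and `newick`
#'   (the dendrogram as a Newick string).
#' @export
hierarchical_order <- function(sim) {
  m <- unclass(sim)
  if (anyNA(m)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(i) {
      paste0(rownames(m)[i[1]], "~", colnames(m)[i[2]])
    })
    stop(sprintf("undefined correlations for: %s",
                 paste(unique(pairs), collapse = ", ")), call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - m), method = "complete")
  phy <- ape::as.phylo(hc)
  structure(list(labels = rownames(m)[hc$order], order = hc$order,
                 hclust = hc,
                 newick = ape::write.tree(phy)),
            class = "param_dendrogram")
}

#' @export
print.param_dendrogram <- function(x, ...) {
  cat("<param_dendrogram>", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Cross-condition similarity of condition-qualified parameters
#'
#' Cells are unpaired across conditions, so parameter vectors from
#' different conditions are compared through within-condition
#' rank-quantile matching: for the entry between `(A, p)` and `(B, q)`,
#' each condition's cells are ordered by the anchor parameter, sampled at
#' a common grid of quantile ranks, and the resulting pseudo-paired
#' vectors are correlated; the two choices of anchor (`p` or `q`) are
#' averaged, which makes the matrix symmetric. Within one condition this
#' construction reduces exactly to the ordinary cell-level Pearson
#' correlation, and a condition compared against a copy of itself
#' reproduces its own within-condition block. Nodes are named
#' `<condition>:<parameter>`.
#'
#' @param table Cell table pooled over conditions.
#' @param parameters Parameters to correlate (as in [pearson_matrix()]).
#' @param population Optional class filter (as in [pearson_matrix()]).
#' @param conditions Conditions to include (default: all in the table).
#' @param n_quantiles Number of quantile-rank grid points (default: the
#'   smallest per-condition cell count, capped at 200).
#' @return A `similarity_matrix` over (condition, parameter) pairs with
#'   attribute `conditions`.
#' @export
cross_condition_similarity <- function(table, parameters,
                                       population = NULL,
                                       conditions = NULL,
                                       n_quantiles = NULL) {
  if (!is.null(population)) {
    cls_col <- if ("pred_class" %in% names(table)) "pred_class"
               else "true_class"
    table <- table[table[[cls_col]] == population, ]
  }
  conditions <- conditions %||% unique(table$condition)
  cols <- ifelse(paste0("mean_", parameters) %in% names(table),
                 paste0("mean_", parameters), parameters)
  missing <- setdiff(cols, names(table))
  abort_if(length(missing) > 0, "columns not in table: %s",
           paste(missing, collapse = ", "))
  ns <- vapply(conditions,
               function(cd) sum(table$condition == cd), 0L)
  abort_if(any(ns < 3), "condition with < 3 cells: %s",
           paste(conditions[ns < 3], collapse = ", "))
  nq <- n_quantiles %||% min(200L, min(ns))
  P <- length(parameters)
  C <- length(conditions)
  # anchored[[cond]][[p]] : nq x P matrix of all parameters of `cond`,
  # rows = cells at matched quantile ranks of anchor parameter p
  anchored <- lapply(conditions, function(cd) {
    X <- as.matrix(table[table$condition == cd, cols])
    gi <- pmin(pmax(round((seq_len(nq) - 0.5) / nq * nrow(X) + 0.5), 1),
               nrow(X))
    lapply(seq_len(P), function(p) X[order(X[, p])[gi], , drop = FALSE])
  })
  names(anchored) <- conditions
  nm <- as.vector(t(outer(conditions, parameters, paste, sep = ":")))
  r <- matrix(NA_real_, C * P, C * P, dimnames = list(nm, nm))
  cor1 <- function(x, y) {
    suppressWarnings(stats::cor(x, y))
  }
  for (i in seq_len(C * P)) {
    for (j in seq_len(i)) {
      ci <- (i - 1) %/% P + 1; pi <- (i - 1) %% P + 1
      cj <- (j - 1) %/% P + 1; pj <- (j - 1) %% P + 1
      r_pi <- cor1(anchored[[ci]][[pi]][, pi], anchored[[cj]][[pi]][, pj])
      r_pj <- cor1(anchored[[ci]][[pj]][, pi], anchored[[cj]][[pj]][, pj])
      r[i, j] <- r[j, i] <- (r_pi + r_pj) / 2
    }
  }
  diag(r) <- 1
  structure(r, n_cells = sum(ns), conditions = conditions,
            n_quantiles = nq, class = "similarity_matrix")
}

#' Correlation network with a strict positive cutoff
#'
#' Builds the undirected graph whose nodes are the parameters of a
#' similarity matrix and whose edges connect pairs with `r > cutoff`
#' (strictly greater; `r == cutoff` draws no edge), weighted by `r`.
#' Self-edges are excluded; an empty graph is valid.
#'
#' @param sim A `similarity_matrix`.
#' @param cutoff Correlation cutoff (default 0.3).
#' @return An [igraph::graph] with edge attribute `weight`.
#' @export
edge_bundle_graph <- function(sim, cutoff = 0.3) {
  m <- unclass(sim)
  idx <- which(upper.tri(m) & !is.na(m) & m > cutoff, arr.ind = TRUE)
  edges <- tibble::tibble(from = rownames(m)[idx[, 1]],
                          to = colnames(m)[idx[, 2]],
                          weight = m[idx])
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble::tibble(name = rownames(m)))
}

#' Export a correlation network
#'
#' `write_graph_json()` writes a node-link JSON document
#' (`{"nodes": [...], "links": [...]}`); `write_graph_graphml()` writes
#' GraphML.
#'
#' @param graph An igraph object from [edge_bundle_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  jsonlite::write_json(
    list(nodes = lapply(igraph::V(graph)$name,
                        function(n) list(id = n)),
         links = lapply(seq_len(nrow(el)), function(i) {
           list(source = el$from[i], target = el$to[i],
                weight = el$weight[i])
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
write_graph_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write a similarity matrix as a labeled square CSV
#' @param sim A `similarity_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  df <- tibble::as_tibble(unclass(sim), rownames = "parameter")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
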