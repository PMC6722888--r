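# Fast Gentle Boosting: an additive model of regression stumps fit by
# weighted least squares with multiplicative weight updates, trained
# one-vs-rest per class. Each stump contributes b + a * (x_j > theta):
# b is the weighted mean response on the low side of the threshold and
# a is the step added on the high side.

# Best stump for one weighted regression problem. `orders` caches the
# per-feature sort permutations. Ties in weighted squared error break
# toward the lowest feature index, then the lowest threshold.
.fit_stump <- function(X, y, w, orders) {
  best <- list(gain = -Inf, feature = NA_integer_, theta = NA_real_,
               a = NA_real_, b = NA_real_)
  for (j in seq_len(ncol(X))) {
    ord <- orders[[j]]
    xs <- X[ord, j]
    ws <- w[ord]
    wys <- ws * y[ord]
    cw <- cumsum(ws)
    cwy <- cumsum(wys)
    W_tot <- cw[length(cw)]
    WY_tot <- cwy[length(cwy)]
    n <- length(xs)
    valid <- which(xs[-n] < xs[-1])          # split between i and i+1
    if (length(valid) == 0) next
    wl <- cw[valid]; wyl <- cwy[valid]
    wr <- W_tot - wl; wyr <- WY_tot - wyl
    gain <- wyl^2 / wl + wyr^2 / wr          # explained weighted SS
    k <- which.max(gain)                      # first max = lowest theta
    if (gain[k] > best$gain) {
      i <- valid[k]
      b <- wyl[k] / wl[k]
      best <- list(gain = gain[k], feature = j,
                   theta = (xs[i] + xs[i + 1]) / 2,
                   a = wyr[k] / wr[k] - b, b = b)
    }
  }
  best
}

#' Train a Fast Gentle Boosting classifier
#'
#' One-vs-rest per class with targets in {-1, +1} and uniform initial
#' weights. Each boosting round selects the (feature, threshold) stump
#' minimizing the weighted squared error of the fit, where the fitted
#' values on the two sides of the threshold are the weighted means of the
#' target; candidate thresholds are the midpoints between consecutive
#' distinct sorted feature values. After each round the example weights
#' are multiplied by `exp(-y * f(x))` and renormalized. Training is
#' deterministic given the input row order, with error ties broken by
#' lowest feature index and then lowest threshold.
#'
#' @param table Cell table carrying the feature columns.
#' @param labels Character vector of class labels, one per row (or the
#'   name of a column of `table`).
#' @param feature_names Feature columns to learn from.
#' @param n_rounds Number of boosting rounds per class (default 50).
#' @return An object of class `fgb_model`: class names (in first-seen
#'   order against the canonical [nuclear_classes()] ordering when
#'   applicable), feature names, per-class stump tables
#'   (`feature`, `threshold`, `a`, `b`), and the per-round training
#'   exponential loss per class.
#' @export
train_fast_gentle_boosting <- function(table, labels, feature_names,
                                       n_rounds = 50) {
  if (length(labels) == 1 && labels %in% names(table)) {
    labels <- table[[labels]]
  }
  abort_if(length(labels) != nrow(table),
           "labels length (%d) does not match table rows (%d)",
           length(labels), nrow(table))
  missing <- setdiff(feature_names, names(table))
  abort_if(length(missing) > 0, "feature columns not in table: %s",
           paste(missing, collapse = ", "))
  tab <- table(labels)
  abort_if(length(tab) < 2, "need at least 2 classes")
  small <- names(tab)[tab < 2]
  abort_if(length(small) > 0, "class with < 2 members: %s",
           paste(small, collapse = ", "))
  canonical <- intersect(nuclear_classes(), names(tab))
  class_names <- c(canonical, setdiff(names(tab), canonical))
  X <- as.matrix(table[, feature_names])
  storage.mode(X) <- "double"
  orders <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  n <- nrow(X)
  stumps <- list()
  losses <- list()
  for (cls in class_names) {
    y <- ifelse(labels == cls, 1, -1)
    w <- rep(1 / n, n)
    Fx <- numeric(n)
    rows <- vector("list", n_rounds)
    loss <- numeric(n_rounds)
    for (t in seq_len(n_rounds)) {
      st <- .fit_stump(X, y, w, orders)
      if (!is.finite(st$gain)) {           # no valid split (constant X)
        st <- list(feature = 1L, theta = Inf, a = 0,
                   b = sum(w * y) / sum(w))
      }
      f <- st$b + st$a * (X[, st$feature] > st$theta)
      Fx <- Fx + f
      w <- w * exp(-y * f)
      w <- w / sum(w)
      rows[[t]] <- tibble::tibble(round = t,
                                  feature = feature_names[st$feature],
                                  threshold = st$theta, a = st$a, b = st$b)
      loss[t] <- mean(exp(-y * Fx))
    }
    stumps[[cls]] <- dplyr::bind_rows(rows)
    losses[[cls]] <- loss
  }
  structure(list(class_names = class_names, feature_names = feature_names,
                 stumps = stumps, n_rounds = n_rounds,
                 training_loss = losses),
            class = "fgb_model")
}

#' @export
print.fgb_model <- function(x, ...) {
  cat(sprintf("<fgb_model> %d classes x %d rounds over %d features\n",
              length(x$class_names), x$n_rounds, length(x$feature_names)))
  invisible(x)
}

# Additive per-class scores for a feature matrix
.fgb_margins <- function(model, X) {
  K <- length(model$class_names)
  M <- matrix(0, nrow(X), K, dimnames = list(NULL, model$class_names))
  for (k in seq_len(K)) {
    st <- model$stumps[[model$class_names[k]]]
    for (t in seq_len(nrow(st))) {
      xj <- X[, st$feature[t]]
      M[, k] <- M[, k] + st$b[t] + st$a[t] * (xj > st$threshold[t])
    }
  }
  M
}

#' Score cells with a trained boosting model
#'
#' Adds a `pred_class` column (argmax of the per-class additive scores,
#' ties broken by class order) and one `score_<class>` margin column per
#' class. A feature exactly at a stump threshold takes the low branch
#' (the comparison is strictly greater-than).
#'
#' @param model An `fgb_model`.
#' @param table Cell table containing all model features.
#' @return The table with `pred_class` and margin columns appended.
#' @export
score_cells <- function(model, table) {
  missing <- setdiff(model$feature_names, names(table))
  abort_if(length(missing) > 0, "missing feature column: %s",
           paste(missing, collapse = ", "))
  X <- as.matrix(table[, model$feature_names])
  storage.mode(X) <- "double"
  M <- .fgb_margins(model, X)
  table$pred_class <- model$class_names[max.col(M, ties.method = "first")]
  for (k in seq_along(model$class_names)) {
    table[[paste0("score_", model$class_names[k])]] <- M[, k]
  }
  table
}

#' Stratified k-fold cross-validation with a pooled confusion matrix
#'
#' Rows are split into `folds` stratified folds (each class shuffled with
#' the given seed and dealt round-robin); out-of-fold predictions are
#' pooled and tabulated into a row-normalized confusion matrix
#' (rows = true class, columns = predicted class).
#'
#' @inheritParams train_fast_gentle_boosting
#' @param folds Number of folds (default 5); every class needs at least
#'   `folds` members.
#' @param seed Integer seed for the fold assignment.
#' @return A K x K matrix of class `confusion_matrix` with attributes
#'   `support` (per-class true counts), `accuracy` (overall), and
#'   `predictions` (tibble of true/predicted labels).
#' @export
cross_validate <- function(table, labels, feature_names, folds = 5,
                           n_rounds = 50, seed = 1) {
  if (length(labels) == 1 && labels %in% names(table)) {
    labels <- table[[labels]]
  }
  abort_if(folds < 2, "folds must be >= 2")
  tab <- table(labels)
  small <- names(tab)[tab < folds]
  abort_if(length(small) > 0,
           "class smaller than fold count (%d): %s", folds,
           paste(small, collapse = ", "))
  fold_of <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    model <- train_fast_gentle_boosting(table[tr, ], labels[tr],
                                        feature_names, n_rounds)
    pred[!tr] <- score_cells(model, table[!tr, ])$pred_class
  }
  canonical <- intersect(nuclear_classes(), names(tab))
  class_names <- c(canonical, setdiff(names(tab), canonical))
  cm <- table(factor(labels, class_names), factor(pred, class_names))
  support <- rowSums(cm)
  norm <- sweep(unclass(cm), 1, pmax(support, 1), "/")
  structure(norm, support = support,
            accuracy = sum(diag(cm)) / sum(cm),
            predictions = tibble::tibble(true = labels, pred = pred),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> accuracy %.3f\n", attr(x, "accuracy")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mitotic index per condition
#'
#' The fraction of detected cells classified as mitotic, pooled over all
#' replicate ROIs of each condition.
#'
#' @param scored Cell table with a class column and `condition`.
#' @param mitotic_class Label counting as mitotic (default
#'   `"pHistone3+"`).
#' @param class_col Column holding the class calls (default
#'   `"pred_class"`).
#' @return A tibble with `condition`, `n_cells`, `n_mitotic`,
#'   `mitotic_index`. Conditions with zero cells are reported as `NA`.
#' @export
mitotic_index <- function(scored, mitotic_class = "pHistone3+",
                          class_col = "pred_class") {
  abort_if(!class_col %in% names(scored),
           "column '%s' not in table", class_col)
  scored |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_mitotic = sum(.data[[class_col]] == mitotic_class),
      mitotic_index = ifelse(.data$n_cells > 0,
                             .data$n_mitotic / .data$n_cells, NA_real_),
      .groups = "drop")
}

#' Tidy a boosting model into its stump table
#'
#' @param x An `fgb_model`.
#' @param ... Ignored.
#' @return A tibble with one row per (class, round) stump:
#'   `class`, `round`, `feature`, `threshold`, `a`, `b`.
#' @export
tidy.fgb_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$class_names, function(cls) {
    dplyr::mutate(x$stumps[[cls]], class = cls, .before = 1)
  }))
}

#' One-row summary of a boosting model
#'
#' @param x An `fgb_model`.
#' @param ... Ignored.
#' @return A tibble with `n_classes`, `n_rounds`, `n_features`, and the
#'   final training exponential loss averaged over classes.
#' @export
glance.fgb_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_names), n_rounds = x$n_rounds,
    n_features = length(x$feature_names),
    final_training_loss = mean(vapply(x$training_loss,
                                      function(l) l[length(l)], 0)))
}

#' @rdname tidy.fgb_model
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    true = rep(rownames(m), times = ncol(m)),
    pred = rep(colnames(m), each = nrow(m)),
    fraction = as.vector(m))
}

#' Serialize / restore a boosting model as JSON
#'
#' @param model An `fgb_model`.
#' @param path JSON path.
#' @return `write_boost_model()` returns `path` invisibly;
#'   `read_boost_model()` returns the model.
#' @export
write_boost_model <- function(model, path) {
  jsonlite::write_json(
    list(class_names = model$class_names,
         feature_names = model$feature_names, n_rounds = model$n_rounds,
         stumps = lapply(model$stumps, as.data.frame),
         training_loss = model$training_loss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(class_names = obj$class_names,
                 feature_names = obj$feature_names,
                 stumps = lapply(obj$stumps, tibble::as_tibble),
                 n_rounds = obj$n_rounds,
                 training_loss = obj$training_loss),
            class = "fgb_model")
}
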