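# brute-force oracle for a single weighted regression stump: scan every
# midpoint threshold, fit both sides by weighted means, return the
# weighted-SSE minimizer (in the b + a*(x > theta) parameterization)
oracle_stump <- function(x, y, w = rep(1 / length(x), length(x))) {
  xs <- sort(unique(x))
  best <- NULL
  for (th in (xs[-1] + xs[-length(xs)]) / 2) {
    hi <- x > th
    b <- sum(w[!hi] * y[!hi]) / sum(w[!hi])
    ab <- sum(w[hi] * y[hi]) / sum(w[hi])
    sse <- sum(w * (y - ifelse(hi, ab, b))^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(theta = th, a = ab - b, b = b, sse = sse)
    }
  }
  best
}

test_that("one boosting round reproduces the closed-form stump", {
  tb <- tibble::tibble(f = c(0, 1, 2, 3))
  y <- c(-1, -1, 1, 1)
  orc <- oracle_stump(tb$f, y)
  expect_equal(orc$theta, 1.5)
  expect_equal(orc$a, 2)
  expect_equal(orc$b, -1)
  m <- train_fast_gentle_boosting(tb, c("A", "A", "B", "B"), "f",
                                  n_rounds = 1)
  st <- m$stumps[["B"]]           # one-vs-rest target +1 for class B
  expect_equal(st$threshold, orc$theta)
  expect_equal(st$a, orc$a)
  expect_equal(st$b, orc$b)
  # and the A-vs-rest stump is its mirror image
  expect_equal(m$stumps[["A"]]$a, -2)
  expect_equal(m$stumps[["A"]]$b, 1)
})

test_that("stump selection matches the oracle over two weighted rounds", {
  wsse <- function(x, y, w, st) {
    sum(w * (y - (st$b + st$a * (x > st$theta)))^2)
  }
  withr::with_seed(17, {
    for (i in 1:5) {
      x <- round(rnorm(30), 1)
      y <- sign(rnorm(30))
      y[y == 0] <- 1
      tb <- tibble::tibble(f = x)
      m <- train_fast_gentle_boosting(tb, ifelse(y > 0, "pos", "neg"),
                                      "f", n_rounds = 2)
      st <- m$stumps[["pos"]]
      # round 1: uniform weights
      w1 <- rep(1 / 30, 30)
      orc1 <- oracle_stump(x, y, w1)
      got1 <- list(theta = st$threshold[1], a = st$a[1], b = st$b[1])
      expect_equal(wsse(x, y, w1, got1), orc1$sse, tolerance = 1e-12)
      # round 2: weights follow the documented multiplicative update
      f1 <- got1$b + got1$a * (x > got1$theta)
      w2 <- w1 * exp(-y * f1)
      w2 <- w2 / sum(w2)
      orc2 <- oracle_stump(x, y, w2)
      got2 <- list(theta = st$threshold[2], a = st$a[2], b = st$b[2])
      expect_equal(wsse(x, y, w2, got2), orc2$sse, tolerance = 1e-12)
    }
  })
})

test_that("a separable problem reaches training accuracy 1 in 5 rounds", {
  tb <- tibble::tibble(f = c(rnorm(20, 0), rnorm(20, 10)),
                       noise = rnorm(40))
  lab <- rep(c("lo", "hi"), each = 20)
  m <- train_fast_gentle_boosting(tb, lab, c("f", "noise"), n_rounds = 5)
  sc <- score_cells(m, tb)
  expect_equal(mean(sc$pred_class == lab), 1)
})

test_that("training is invariant to row permutation", {
  tb <- mini_truth_table()
  feats <- c(intensity_columns(tb), size_columns())
  m1 <- train_fast_gentle_boosting(tb, tb$true_class, feats, n_rounds = 10)
  perm <- withr::with_seed(2, sample(nrow(tb)))
  m2 <- train_fast_gentle_boosting(tb[perm, ], tb$true_class[perm], feats,
                                   n_rounds = 10)
  expect_equal(m1$stumps, m2$stumps)
})

test_that("exactly-at-threshold features take the low branch", {
  model <- structure(list(
    class_names = c("lo", "hi"), feature_names = "f",
    stumps = list(lo = tibble::tibble(round = 1L, feature = "f",
                                      threshold = 2, a = -2, b = 1),
                  hi = tibble::tibble(round = 1L, feature = "f",
                                      threshold = 2, a = 2, b = -1)),
    n_rounds = 1L), class = "fgb_model")
  sc <- score_cells(model, tibble::tibble(f = c(2, 2.0001)))
  expect_equal(sc$pred_class, c("lo", "hi"))   # strict > at theta
})

test_that("training loss is non-increasing over boosting rounds", {
  tb <- mini_truth_table()
  feats <- c(intensity_columns(tb), size_columns())
  m <- train_fast_gentle_boosting(tb, tb$true_class, feats, n_rounds = 25)
  for (cls in m$class_names) {
    expect_true(all(diff(m$training_loss[[cls]]) <= 1e-10))
  }
})

test_that("scoring the training set reproduces training-time margins", {
  tb <- mini_truth_table()
  feats <- c(intensity_columns(tb), size_columns())
  m <- train_fast_gentle_boosting(tb, tb$true_class, feats, n_rounds = 10)
  s1 <- score_cells(m, tb)
  s2 <- score_cells(m, tb)
  expect_identical(s1, s2)
})

test_that("missing feature columns are named in the error", {
  m <- train_fast_gentle_boosting(tibble::tibble(f = c(0, 1, 2, 3)),
                                  c("A", "A", "B", "B"), "f", 1)
  expect_error(score_cells(m, tibble::tibble(g = 1:3)), "f")
})

test_that("degenerate classes are rejected", {
  tb <- tibble::tibble(f = 1:3)
  expect_error(train_fast_gentle_boosting(tb, c("A", "A", "B"), "f", 1),
               "< 2 members")
  expect_error(train_fast_gentle_boosting(tb, c("A", "A", "A"), "f", 1),
               "2 classes")
})

test_that("cross-validation separates separable classes perfectly", {
  tb <- tibble::tibble(f = c(rnorm(30, 0), rnorm(30, 10)))
  lab <- rep(c("lo", "hi"), each = 30)
  cm <- cross_validate(tb, lab, "f", folds = 5, n_rounds = 5, seed = 1)
  expect_equal(unclass(cm), diag(2), ignore_attr = TRUE)
  expect_equal(rowSums(cm), c(hi = 1, lo = 1), ignore_attr = TRUE)
})

test_that("null labels give chance-level cross-validation (no leakage)", {
  tb <- mini_truth_table()
  feats <- c(intensity_columns(tb), size_columns())
  K <- 6
  null_lab <- withr::with_seed(5, sample(rep_len(nuclear_classes(),
                                                 nrow(tb))))
  cm <- cross_validate(tb, null_lab, feats, folds = 5, n_rounds = 10,
                       seed = 2)
  expect_equal(rowSums(cm), rep(1, K), ignore_attr = TRUE,
               tolerance = 1e-9)
  supp <- attr(cm, "support")
  for (k in seq_len(K)) {
    se <- sqrt((1 / K) * (1 - 1 / K) / supp[k])
    expect_lt(abs(unclass(cm)[k, k] - 1 / K), 3 * se + 0.02)
  }
})

test_that("cross-validation rejects classes smaller than the fold count", {
  tb <- tibble::tibble(f = 1:10)
  lab <- c(rep("A", 7), rep("B", 3))
  expect_error(cross_validate(tb, lab, "f", folds = 5), "smaller")
})

test_that("mitotic index is exact per-condition arithmetic", {
  sc <- tibble::tibble(
    condition = rep(c("noc", "ctl"), c(1000, 500)),
    pred_class = c(rep("pHistone3+", 30), rep("negative", 970),
                   rep("negative", 500)))
  mi <- mitotic_index(sc)
  expect_equal(mi$mitotic_index[mi$condition == "noc"], 0.03)
  expect_equal(mi$mitotic_index[mi$condition == "ctl"], 0)
})

test_that("models serialize to JSON and back without changing calls", {
  tb <- mini_truth_table()
  feats <- c(intensity_columns(tb), size_columns())
  m <- train_fast_gentle_boosting(tb, tb$true_class, feats, n_rounds = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_boost_model(m, f)
  m2 <- read_boost_model(f)
  expect_identical(score_cells(m, tb)$pred_class,
                   score_cells(m2, tb)$pred_class)
  expect_equal(glance(m)$n_rounds, 8)
  td <- tidy(m)
  expect_true(all(c("class", "round", "feature", "threshold", "a", "b")
                  %in% names(td)))
  expect_equal(nrow(td), 8 * 6)
})
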