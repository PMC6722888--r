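# two-pass covariance oracle for Pearson correlation
oracle_cor <- function(X) {
  P <- ncol(X)
  out <- matrix(NA_real_, P, P, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      xi <- X[, i] - mean(X[, i])
      xj <- X[, j] - mean(X[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

test_that("pearson matrix matches identities and hand computation", {
  tb <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
                       w = c(4, 3, 2, 1))
  sim <- pearson_matrix(tb, c("x", "y", "w"))
  expect_equal(unclass(sim)["x", "y"], 1)
  expect_equal(unclass(sim)["x", "w"], -1)
  expect_equal(diag(unclass(sim)), c(x = 1, y = 1, w = 1))
  expect_true(all(abs(unclass(sim)) <= 1 + 1e-12))
})

test_that("pearson matrix agrees with the covariance oracle to 1e-12", {
  withr::with_seed(31, {
    X <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(NULL, paste0("p", 1:8)))
    tb <- tibble::as_tibble(as.data.frame(X))
    sim <- pearson_matrix(tb, paste0("p", 1:8))
    expect_equal(unclass(sim), oracle_cor(X), tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("population filtering and the minimum-cell rule apply", {
  tb <- tibble::tibble(pred_class = c("a", "a", "a", "b", "b"),
                       x = c(1, 2, 3, 4, 5), y = c(5, 4, 3, 2, 1))
  sim <- pearson_matrix(tb, c("x", "y"), population = "a")
  expect_equal(attr(sim, "n_cells"), 3)
  expect_error(pearson_matrix(tb, c("x", "y"), population = "b"),
               "at least 3")
})

test_that("constant columns stay missing and block clustering by name", {
  tb <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3),
                       k = c(7, 7, 7, 7))
  sim <- pearson_matrix(tb, c("x", "y", "k"))
  expect_true(is.na(unclass(sim)["x", "k"]))
  expect_equal(unclass(sim)["k", "k"], 1)
  expect_error(hierarchical_order(sim), "x~k|k~x")
})

test_that("perfectly correlated parameters merge first at height 0", {
  tb <- tibble::tibble(x = c(1, 2, 3, 5), y = c(2, 4, 6, 10),
                       z = c(9, 1, 4, 2))
  ord <- hierarchical_order(pearson_matrix(tb, c("x", "y", "z")))
  expect_equal(ord$hclust$height[1], 0, tolerance = 1e-12)
  # the first merge joins the two perfectly correlated leaves x and y
  first_leaves <- -ord$hclust$merge[1, ]
  expect_setequal(c("x", "y", "z")[first_leaves], c("x", "y"))
  expect_match(ord$newick, "^\\(")
})

test_that("leaf order is invariant to cell-row shuffling", {
  tab <- mini_truth_table()
  params <- c("Ir191-DNA", "Ir193-DNA", "pHistone3-S28", "Ki-67",
              "p4E-BP1", "CD29", "CD81", "CD98", "pan-keratin", "CK19")
  o1 <- hierarchical_order(pearson_matrix(tab, params,
                                          population = "pHistone3+"))
  perm <- withr::with_seed(4, sample(nrow(tab)))
  o2 <- hierarchical_order(pearson_matrix(tab[perm, ], params,
                                          population = "pHistone3+"))
  expect_identical(o1$labels, o2$labels)
})

test_that("planted latent factors shape the mitotic similarity structure", {
  tab <- big_truth_table()
  params <- c("Ir191-DNA", "Ir193-DNA", "pHistone3-S28", "pH2A.X-S139",
              "Ki-67", "p53", "cyclinB1", "cyclinD3", "p4E-BP1", "cPARP",
              "pan-keratin", "CK19", "CD29", "CD81", "CD98", "CD47",
              "CD49e", "EpCAM", size_columns())
  sim <- pearson_matrix(tab, params, population = "pHistone3+")
  m <- unclass(sim)
  mit <- c("pHistone3-S28", "Ki-67", "p4E-BP1")
  cd <- c("CD29", "CD81", "CD98", "CD47", "CD49e", "EpCAM")
  off_diag_mean <- function(block) {
    mean(block[upper.tri(block)])
  }
  r_mit <- off_diag_mean(m[mit, mit])
  r_cd <- off_diag_mean(m[cd, cd])
  r_between <- mean(m[mit, cd])
  expect_gt(r_mit, 0)
  expect_gt(r_cd, r_between)
  # the two intercalator isotopes end as adjacent leaves
  ord <- hierarchical_order(sim)
  i1 <- match("Ir191-DNA", ord$labels)
  i2 <- match("Ir193-DNA", ord$labels)
  expect_equal(abs(i1 - i2), 1)
  # the mitotic trio forms one contiguous leaf block
  pos <- sort(match(mit, ord$labels))
  expect_equal(pos[3] - pos[1], 2)
})

test_that("a duplicated condition reproduces its own similarity block", {
  tab <- mini_truth_table()
  sub <- tab[tab$condition == "nontreated", ]
  dup <- dplyr::mutate(sub, condition = "copy")
  both <- dplyr::bind_rows(sub, dup)
  params <- c("CD29", "CD81", "CD98")
  sim <- cross_condition_similarity(both, params,
                                    conditions = c("nontreated", "copy"))
  m <- unclass(sim)
  a <- paste0("nontreated:", params)
  b <- paste0("copy:", params)
  expect_equal(m[a, a], m[a, b], ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(abs(m) <= 1 + 1e-12))
})

test_that("control conditions resemble each other more than EGF", {
  tab <- big_truth_table()
  params <- c("CD98", "CD29", "EpCAM", "CD81", "CD47", "CD49e")
  sim <- cross_condition_similarity(tab, params,
                                    population = "pHistone3+",
                                    conditions = c("nontreated", "DMSO",
                                                   "EGF"))
  m <- unclass(sim)
  blk <- function(c1, c2) {
    mean(m[paste0(c1, ":", params), paste0(c2, ":", params)])
  }
  expect_gt(blk("nontreated", "DMSO"), blk("nontreated", "EGF"))
})

test_that("the correlation network applies a strict cutoff", {
  m <- matrix(c(1, 0.9, 0.3, 0.9, 1, 0.1, 0.3, 0.1, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- edge_bundle_graph(structure(m, class = "similarity_matrix"),
                         cutoff = 0.3)
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 1)          # only a-b; r = 0.3 excluded
  e <- igraph::as_data_frame(g)
  expect_setequal(c(e$from, e$to), c("a", "b"))
  expect_equal(e$weight, 0.9)
  # all r <= cutoff -> empty graph is valid
  low <- structure(diag(3), dimnames = dimnames(m),
                   class = "similarity_matrix")
  expect_equal(igraph::gsize(edge_bundle_graph(low, cutoff = 0.3)), 0)
})

test_that("graph and similarity exports are readable", {
  tb <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 4, 5, 9),
                       w = c(4, 3, 2, 1))
  sim <- pearson_matrix(tb, c("x", "y", "w"))
  g <- edge_bundle_graph(sim)
  fj <- withr::local_tempfile(fileext = ".json")
  fg <- withr::local_tempfile(fileext = ".graphml")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_graph_json(g, fj)
  doc <- jsonlite::read_json(fj)
  expect_length(doc$nodes, 3)
  write_graph_graphml(g, fg)
  expect_gt(file.size(fg), 0)
  write_similarity(sim, fc)
  back <- readr::read_csv(fc, show_col_types = FALSE)
  expect_equal(back$parameter, c("x", "y", "w"))
  expect_equal(back$x, unname(unclass(sim)[, "x"]), tolerance = 1e-12)
})
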