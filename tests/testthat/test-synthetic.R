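test_that("treatment profiles validate their invariants", {
  expect_error(treatment_profile("x", -1, c(negative = 1), 180, 40, 0.5,
                                 list()), "cell_density")
  expect_error(treatment_profile("x", 600, c(a = 0.5, b = 0.6), 180, 40,
                                 0.5, list()), "sum to 1")
  expect_error(treatment_profile("x", 600, c(negative = 1), 180, 40, 1.2,
                                 list()), "nucleus_fraction")
  for (pr in default_profiles()) {
    expect_equal(sum(pr$class_mixture), 1, tolerance = 1e-12)
    expect_true(all(unlist(pr$expression) >= 0))
  }
})

test_that("cell layout is deterministic and respects the class mixture", {
  prof <- default_profiles()$nontreated
  a <- sample_cell_layout(prof, c(500, 500), seed = 1)
  b <- sample_cell_layout(prof, c(500, 500), seed = 1)
  expect_identical(a, b)
  # empirical class frequencies within 3 binomial SE of the mixture
  n <- nrow(a)
  for (cls in names(prof$class_mixture)) {
    p <- prof$class_mixture[[cls]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(a$class == cls) - p), 3 * se + 1e-12)
  }
  # cells fit in the ROI and nuclei sit strictly inside cells
  expect_true(all(a$x - pmax(a$cell_a, a$cell_b) >= 0))
  expect_true(all(a$nuc_a < a$cell_a & a$nuc_b < a$cell_b))
})

test_that("a zero-density-equivalent layout may be empty", {
  prof <- test_profile(cell_density = 1)   # ~0 cells expected in 50x50 um
  lay <- sample_cell_layout(prof, c(50, 50), seed = 1)
  expect_true(nrow(lay) >= 0)
  expect_s3_class(lay, "tbl_df")
})

test_that("infeasible density errors with achieved vs requested", {
  prof <- test_profile(cell_density = 50000)
  expect_error(sample_cell_layout(prof, c(100, 100), seed = 1),
               "achieved.*requested|infeasible")
})

test_that("empty cell list renders pure Poisson background", {
  empty <- sample_cell_layout(test_profile(cell_density = 1), c(40, 40),
                              seed = 1)
  skip_if(nrow(empty) > 0)
  roi <- render_roi(empty, test_panel(), c(64, 64), seed = 9,
                    background_lambda = 0.5)
  x <- roi$stack$pixels
  expect_true(all(x >= 0) && all(x == round(x)))
  # sample mean within 3 SE of lambda for each channel
  se <- sqrt(0.5 / (64 * 64))
  for (k in 1:5) expect_lt(abs(mean(x[, , k]) - 0.5), 3 * se)
  expect_equal(nrow(roi$truth_table), 0)
})

test_that("a planted nucleus recovers its rate over truth pixels", {
  cells <- tibble::tibble(cell_id = 1L, x = 32, y = 32, cell_a = 12,
                          cell_b = 10, theta = 0.3, nuc_a = 8, nuc_b = 6.7,
                          class = "negative",
                          lambda = list(c(dna = 50, cyto = 15, mem = 8)))
  roi <- render_roi(cells, test_panel(), c(64, 64), seed = 4,
                    background_lambda = 0.5)
  nuc_px <- which(unclass(roi$truth_nuclei) > 0)
  dna <- roi$stack$pixels[, , 1][nuc_px]
  se <- sqrt(50.5 / length(nuc_px))
  expect_lt(abs(mean(dna) - 50.5), 3 * se)
  # nuclear marker confined to the nucleus: outside-cell pixels are
  # background only
  bg_px <- which(unclass(roi$truth_cells) == 0)
  expect_lt(mean(roi$stack$pixels[, , 1][bg_px]), 1)
  # membrane rim deposits only inside the cell, outside the shrunken core
  mem <- roi$stack$pixels[, , 3]
  expect_gt(mean(mem[unclass(roi$truth_cells) > 0]), mean(mem[bg_px]))
})

test_that("unknown compartment class errors at render", {
  bad_panel <- tibble::tibble(metal_tag = "X1", marker = "x",
                              compartment = "wall")
  cells <- tibble::tibble(cell_id = 1L, x = 20, y = 20, cell_a = 8,
                          cell_b = 7, theta = 0, nuc_a = 5, nuc_b = 4.5,
                          class = "negative", lambda = list(c(x = 5)))
  expect_error(render_roi(cells, bad_panel, c(40, 40), seed = 1),
               "compartment")
})

test_that("truth masks and truth table are mutually consistent", {
  roi <- mini_experiment()[[1]]
  cm <- unclass(roi$truth_cells)
  nm <- unclass(roi$truth_nuclei)
  expect_identical(mask_labels(roi$truth_cells),
                   mask_labels(roi$truth_nuclei))
  expect_identical(roi$truth_table$cell_id,
                   mask_labels(roi$truth_cells))
  # per-label pixel counts equal the area column
  counts <- table(cm[cm > 0])
  expect_equal(as.numeric(counts[as.character(roi$truth_table$cell_id)]),
               roi$truth_table$area_um2)
  # nucleus subset of cell for every label
  idx <- which(nm > 0)
  expect_true(all(cm[idx] == nm[idx]))
})

test_that("planted per-class rates are recovered from truth pixels", {
  rois <- mini_experiment()
  prof <- default_profiles()$nontreated
  roi <- rois[["nontreated_r1"]]
  # pooled nucleus pixels of negative-class cells on the DNA channel:
  # mean-one jitter keeps the expected pixel rate at the profile value
  neg <- roi$truth_table$cell_id[roi$truth_table$true_class == "negative"]
  px <- which(matrix(unclass(roi$truth_nuclei) %in% neg,
                     nrow(roi$truth_nuclei)))
  lam <- prof$expression$negative[["Ir191-DNA"]] + prof$background_lambda
  dna <- get_channel(roi$stack, "Ir191-DNA")[px]
  # per-cell latent factors inflate the variance well beyond Poisson, so
  # bound with the empirical SE of per-pixel counts
  se <- stats::sd(dna) / sqrt(length(dna)) +
    lam * 0.5 / sqrt(length(neg))
  expect_lt(abs(mean(dna) - lam), 3 * se)
})

test_that("experiment generation is deterministic and validates input", {
  a <- generate_experiment(replicates = c(nontreated = 1),
                           roi_size = c(150, 150), master_seed = 5)
  b <- generate_experiment(replicates = c(nontreated = 1),
                           roi_size = c(150, 150), master_seed = 5)
  expect_identical(a[[1]]$stack$pixels, b[[1]]$stack$pixels)
  expect_identical(a[[1]]$truth_table, b[[1]]$truth_table)
  expect_error(generate_experiment(replicates = c(unknown_drug = 1),
                                   roi_size = c(100, 100)),
               "unknown_drug")
  expect_error(generate_experiment(replicates = c(nontreated = 0)),
               ">= 1")
})

test_that("default experiment has the replicate layout of the study", {
  rois <- big_experiment()
  expect_length(rois, 8)
  conds <- vapply(rois, function(r) r$stack$condition, "")
  expect_equal(sum(conds == "nocodazole"), 2)
  expect_equal(sum(conds == "nontreated"), 1)
  expect_equal(sum(conds == "DMSO"), 1)
})

test_that("nocodazole plants ~3x the control mitotic fraction", {
  tab <- big_truth_table()
  f <- function(cond) {
    sub <- tab[tab$condition == cond, ]
    mean(sub$true_class == "pHistone3+")
  }
  noco <- f("nocodazole")
  ctrl <- mean(tab$true_class[tab$condition %in%
                                c("nontreated", "DMSO")] == "pHistone3+")
  n_noco <- sum(tab$condition == "nocodazole")
  se <- sqrt(0.12 * 0.88 / n_noco) + sqrt(0.04 * 0.96 / 300) * 3
  expect_lt(abs(noco - 3 * ctrl), 3 * se)
})
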