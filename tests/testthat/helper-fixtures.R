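# Shared fixtures, built in code and memoized for the duration of a test
# run. The "big" experiment is the default five-condition layout used by
# the acceptance checks; the "mini" experiment is a smaller three-
# condition layout for module-level tests.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small 5-channel panel covering all compartment classes
test_panel <- function() {
  imc_panel(metal_tag = c("Ir191", "Nd148", "Nd150", "Rh103", "Pt195"),
            marker = c("dna", "cyto", "mem", "via", "blank"),
            compartment = c("nucleus", "cytoplasm", "membrane", "any",
                            "any"))
}

# one-class profile on the small panel
test_profile <- function(cell_density = 600, dna = 50, cyto = 15,
                         mem = 8) {
  treatment_profile(
    name = "test", cell_density = cell_density,
    class_mixture = c("negative" = 1),
    area_mean = 180, area_sd = 40, nucleus_fraction = 0.45,
    expression = list(negative = c(dna = dna, cyto = cyto, mem = mem)),
    background_lambda = 0.2)
}

# default five-condition experiment at the package's study conditions
big_experiment <- function() {
  memo("big_experiment", generate_experiment(master_seed = 42))
}

big_truth_table <- function() {
  memo("big_truth_table",
       dplyr::bind_rows(lapply(big_experiment(),
                               function(r) r$truth_table)))
}

# three-condition experiment for module tests
mini_experiment <- function() {
  memo("mini_experiment",
       generate_experiment(replicates = c(nontreated = 1, etoposide = 1,
                                          nocodazole = 1),
                           roi_size = c(400, 400), master_seed = 11))
}

mini_truth_table <- function() {
  memo("mini_truth_table",
       dplyr::bind_rows(lapply(mini_experiment(),
                               function(r) r$truth_table)))
}

# well-separated two-cluster feature table for embedding/classifier tests
gaussian_clusters <- function(n_per = 120, d = 8, p = 5, seed = 3) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per * p), n_per, p),
               matrix(stats::rnorm(n_per * p, mean = d), n_per, p))
    tb <- tibble::as_tibble(as.data.frame(X),
                            .name_repair = ~ paste0("z_f", seq_len(p)))
    tb$cell_id <- seq_len(2 * n_per)
    tb$group <- rep(c("a", "b"), each = n_per)
    tb
  })
}

# build a stack directly from a named list of H x W matrices on the
# test panel (no noise) -- for constructed segmentation/feature fixtures
stack_from_matrices <- function(mats, panel = test_panel(), ...) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  px <- array(0, c(H, W, nrow(panel)))
  for (nm in names(mats)) {
    px[, , match(nm, panel$marker)] <- mats[[nm]]
  }
  imc_stack(px, panel, ...)
}

# paint a filled disk of value v onto a matrix
add_disk <- function(m, cx, cy, r, v) {
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- m[i, j] + v
    }
  }
  m
}
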