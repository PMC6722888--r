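#' Define a treatment profile for the synthetic monolayer generator
#'
#' A treatment profile fixes everything the generator needs to emulate one
#' culture condition: how densely cells grow, how the six nuclear phenotype
#' classes are mixed, how large cells are, and the mean ion count per pixel
#' each class deposits in each channel's compartment.
#'
#' @param name Condition label (e.g. `"nocodazole"`).
#' @param cell_density Target density in cells per mm^2; must be positive.
#' @param class_mixture Named probability vector over the six nuclear
#'   classes (`pHistone3+`, `pH2A.X+`, `p53+`, `cyclinD3+`, `Ki-67+`,
#'   `negative`); must sum to 1.
#' @param area_mean,area_sd Cell area distribution in um^2.
#' @param nucleus_fraction Nuclear/cell area ratio, strictly in (0, 1).
#' @param expression Named list mapping each class to a named numeric
#'   vector of per-pixel mean ion counts (lambda) per marker. Markers not
#'   listed deposit nothing beyond background.
#' @param background_lambda Mean background count per pixel.
#' @param correlation_spec List of channel groups whose per-cell rates
#'   co-vary through a shared log-normal latent factor. Each element is a
#'   list with `channels` (marker names), `sigma` (latent log-sd) and
#'   `classes` (classes it applies to, or `NULL` for all).
#' @return An object of class `treatment_profile`.
#' @export
treatment_profile <- function(name, cell_density, class_mixture,
                              area_mean, area_sd, nucleus_fraction,
                              expression, background_lambda = 0.2,
                              correlation_spec = list()) {
  abort_if(cell_density <= 0, "cell_density must be positive")
  abort_if(abs(sum(class_mixture) - 1) > 1e-9,
           "class_mixture must sum to 1 (got %.12f)", sum(class_mixture))
  abort_if(any(class_mixture < 0), "class_mixture must be nonnegative")
  abort_if(is.null(names(class_mixture)) || anyDuplicated(names(class_mixture)),
           "class_mixture must have unique class names")
  abort_if(nucleus_fraction <= 0 || nucleus_fraction >= 1,
           "nucleus_fraction must lie strictly in (0, 1)")
  abort_if(area_mean <= 0 || area_sd < 0, "invalid area parameters")
  abort_if(background_lambda < 0, "background_lambda must be >= 0")
  for (cls in names(expression)) {
    abort_if(any(expression[[cls]] < 0),
             "expression rates must be >= 0 (class %s)", cls)
  }
  structure(list(name = as.character(name), cell_density = cell_density,
                 class_mixture = class_mixture, area_mean = area_mean,
                 area_sd = area_sd, nucleus_fraction = nucleus_fraction,
                 expression = expression,
                 background_lambda = background_lambda,
                 correlation_spec = correlation_spec),
            class = "treatment_profile")
}

#' @export
print.treatment_profile <- function(x, ...) {
  cat(sprintf("<treatment_profile> %s: %g cells/mm^2, area %g +/- %g um^2\n",
              x$name, x$cell_density, x$area_mean, x$area_sd))
  cat("  class mixture:",
      paste(sprintf("%s=%.2f", names(x$class_mixture), x$class_mixture),
            collapse = " "), "\n")
  invisible(x)
}

#' The six nuclear phenotype classes, in canonical order
#' @export
nuclear_classes <- function() {
  c("pHistone3+", "pH2A.X+", "p53+", "cyclinD3+", "Ki-67+", "negative")
}

# Per-pixel mean count for every (class, marker) pair of the default
# MCF-7 emulation; returns a named list class -> named numeric.
# Every class deposits DNA intercalator in the nucleus, cytokeratins in
# the cytoplasm and adhesion markers on the membrane; each class-defining
# nuclear marker is strongly elevated in its own class. Mitotic cells
# additionally carry elevated Ki-67, p4E-BP1 and cyclin B1.
.default_expression <- function() {
  base <- c("Ir191-DNA" = 40, "Ir193-DNA" = 40,
            "pHistone3-S28" = 0.5, "pH2A.X-S139" = 0.5, "Ki-67" = 1,
            "p53" = 1, "cyclinB1" = 1, "cyclinD3" = 1, "p4E-BP1" = 1,
            "cPARP" = 0.5, "ERalpha" = 4,
            "pan-keratin" = 15, "CK19" = 12, "CD107b" = 2,
            "vimentin" = 0.5, "CK5" = 0.5,
            "MUC-1" = 5, "EpCAM" = 8, "CD29" = 8, "CD81" = 8, "CD98" = 8,
            "CD47" = 8, "CD49e" = 8, "E-cadherin" = 6, "EGFR" = 1.5,
            "HER2" = 2.5)
  ex <- list()
  for (cls in nuclear_classes()) ex[[cls]] <- base
  ex[["pHistone3+"]][c("pHistone3-S28", "Ki-67", "p4E-BP1", "cyclinB1")] <-
    c(30, 15, 12, 8)
  ex[["pH2A.X+"]]["pH2A.X-S139"] <- 25
  ex[["p53+"]]["p53"] <- 20
  ex[["cyclinD3+"]]["cyclinD3"] <- 20
  ex[["Ki-67+"]]["Ki-67"] <- 20
  ex
}

.membrane_markers <- function() {
  c("CD29", "CD81", "CD98", "CD47", "CD49e", "EpCAM", "E-cadherin",
    "MUC-1", "EGFR", "HER2")
}

#' Default treatment profiles for the five-condition MCF-7 experiment
#'
#' Encodes the planted drug effects: the DMSO control matches the
#' nontreated control; nocodazole triples the mitotic (`pHistone3+`)
#' mixture weight (0.04 -> 0.12) and doubles the pHistone3 rate within
#' mitotic cells; etoposide raises the pH2A.X rate fivefold and the
#' `Ki-67+` weight to 0.30; EGF scales mean cell area by 1.8 and membrane
#' marker rates by 1.5 with a wider membrane latent factor. Mitotic cells
#' share one log-normal latent factor across pHistone3/Ki-67/p4E-BP1, and
#' all cells share a second, independent factor across the CD adhesion
#' markers.
#'
#' @return Named list of [treatment_profile()] objects
#'   (`nontreated`, `DMSO`, `EGF`, `etoposide`, `nocodazole`).
#' @export
default_profiles <- function() {
  mix_ctrl <- c("pHistone3+" = 0.04, "pH2A.X+" = 0.10, "p53+" = 0.12,
                "cyclinD3+" = 0.14, "Ki-67+" = 0.22, "negative" = 0.38)
  mix_noco <- c("pHistone3+" = 0.12, "pH2A.X+" = 0.10, "p53+" = 0.12,
                "cyclinD3+" = 0.18, "Ki-67+" = 0.14, "negative" = 0.34)
  mix_etop <- c("pHistone3+" = 0.04, "pH2A.X+" = 0.10, "p53+" = 0.12,
                "cyclinD3+" = 0.14, "Ki-67+" = 0.30, "negative" = 0.30)
  cd_group <- c("CD29", "CD81", "CD98", "CD47", "CD49e", "EpCAM")
  # the two Ir isotopes report one intercalator reagent and the two
  # cytokeratin antibodies detect co-expressed isoforms, so each pair
  # shares a per-cell abundance factor in every condition
  shared_groups <- list(
    list(channels = c("pHistone3-S28", "Ki-67", "p4E-BP1"), sigma = 0.5,
         classes = "pHistone3+"),
    list(channels = c("Ir191-DNA", "Ir193-DNA"), sigma = 0.35,
         classes = NULL),
    list(channels = c("pan-keratin", "CK19"), sigma = 0.35, classes = NULL)
  )
  corr <- c(shared_groups,
            list(list(channels = cd_group, sigma = 0.4, classes = NULL)))
  # EGF remodels adhesion: the integrin regulators CD98/CD47 decouple
  # from the rest of the surface cluster (two independent factors)
  corr_egf <- c(shared_groups, list(
    list(channels = setdiff(cd_group, c("CD98", "CD47")), sigma = 0.5,
         classes = NULL),
    list(channels = c("CD98", "CD47"), sigma = 0.5, classes = NULL)))
  ex <- .default_expression()

  ex_noco <- ex
  ex_noco[["pHistone3+"]]["pHistone3-S28"] <- 60

  ex_etop <- lapply(ex, function(v) {
    v["pH2A.X-S139"] <- v["pH2A.X-S139"] * 5
    v
  })

  ex_egf <- lapply(ex, function(v) {
    m <- intersect(.membrane_markers(), names(v))
    v[m] <- v[m] * 1.5
    v
  })

  mk <- function(name, mix, expr, area_mean = 180, cs = corr) {
    treatment_profile(name = name, cell_density = 600, class_mixture = mix,
                      area_mean = area_mean, area_sd = 50,
                      nucleus_fraction = 0.45, expression = expr,
                      background_lambda = 0.2, correlation_spec = cs)
  }
  list(
    nontreated = mk("nontreated", mix_ctrl, ex),
    DMSO       = mk("DMSO", mix_ctrl, ex),
    EGF        = mk("EGF", mix_ctrl, ex_egf, area_mean = 180 * 1.8,
                    cs = corr_egf),
    etoposide  = mk("etoposide", mix_etop, ex_etop),
    nocodazole = mk("nocodazole", mix_noco, ex_noco)
  )
}

#' Sample a non-overlapping cell layout for one ROI
#'
#' Places cell ellipses by dart throwing until the profile's target density
#' is reached or the attempt budget is exhausted, draws each cell's nuclear
#' class from the profile mixture, and draws per-channel mean rates from
#' the expression map with mean-one log-normal jitter (CV 0.3) plus any
#' shared latent factors from `correlation_spec`.
#'
#' @param profile A [treatment_profile()].
#' @param roi_size `(width, height)` of the ROI in micrometres.
#' @param seed Integer seed; the layout is a pure function of
#'   `(profile, roi_size, seed)`.
#' @return A tibble with one row per cell: `cell_id`, center `x`/`y` (um),
#'   cell and nucleus semi-axes (`cell_a`, `cell_b`, `nuc_a`, `nuc_b`, um),
#'   `theta` (radians), `class`, and a `lambda` list-column of named
#'   per-channel rates.
#' @export
sample_cell_layout <- function(profile, roi_size = c(500, 500), seed = 1) {
  abort_if(any(roi_size <= 0), "roi_size must be positive")
  area_mm2 <- prod(roi_size) / 1e6
  n_target <- round(profile$cell_density * area_mm2)
  withr::with_seed(seed, {
    placed <- list()
    xs <- ys <- rs <- numeric(0)
    attempts <- 0L
    budget <- max(1000L, 60L * n_target)
    while (length(placed) < n_target && attempts < budget) {
      attempts <- attempts + 1L
      area <- stats::rnorm(1, profile$area_mean, profile$area_sd)
      if (area < 40) next
      q <- stats::runif(1, 0.65, 0.95)            # minor/major axis ratio
      a <- sqrt(area / (pi * q))                  # semi-major, um
      b <- q * a
      if (2 * a >= min(roi_size)) next
      x <- stats::runif(1, a, roi_size[1] - a)
      y <- stats::runif(1, a, roi_size[2] - a)
      r_eff <- sqrt(a * b)
      if (length(xs) > 0) {
        d2 <- (xs - x)^2 + (ys - y)^2
        if (any(d2 < (0.9 * (rs + r_eff))^2)) next
      }
      theta <- stats::runif(1, 0, pi)
      f <- sqrt(profile$nucleus_fraction)
      placed[[length(placed) + 1L]] <-
        list(x = x, y = y, a = a, b = b, theta = theta,
             na = f * a, nb = f * b)
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r_eff)
    }
    n <- length(placed)
    if (n_target > 0 && n < 0.8 * n_target) {
      stop(sprintf(paste0("infeasible cell density: achieved %.0f cells/mm^2",
                          " of requested %.0f for ROI %g x %g um"),
                   n / area_mm2, profile$cell_density,
                   roi_size[1], roi_size[2]), call. = FALSE)
    }
    if (n == 0) {
      return(tibble::tibble(cell_id = integer(0), x = numeric(0),
                            y = numeric(0), cell_a = numeric(0),
                            cell_b = numeric(0), theta = numeric(0),
                            nuc_a = numeric(0), nuc_b = numeric(0),
                            class = character(0), lambda = list()))
    }
    classes <- sample(names(profile$class_mixture), n, replace = TRUE,
                      prob = profile$class_mixture)
    sigma0 <- sqrt(log(1 + 0.3^2))                # log-sd for CV 0.3
    lambda <- vector("list", n)
    for (i in seq_len(n)) {
      lam <- profile$expression[[classes[i]]]
      if (is.null(lam)) lam <- numeric(0)
      if (length(lam) > 0) {
        jit <- exp(stats::rnorm(length(lam), 0, sigma0) - sigma0^2 / 2)
        lam <- lam * jit
      }
      for (g in profile$correlation_spec) {
        if (!is.null(g$classes) && !(classes[i] %in% g$classes)) next
        ch <- intersect(g$channels, names(lam))
        if (length(ch) == 0) next
        fac <- exp(stats::rnorm(1, 0, g$sigma) - g$sigma^2 / 2)
        lam[ch] <- lam[ch] * fac
      }
      lambda[[i]] <- lam
    }
    tibble::tibble(
      cell_id = seq_len(n),
      x = purrr::map_dbl(placed, "x"), y = purrr::map_dbl(placed, "y"),
      cell_a = purrr::map_dbl(placed, "a"),
      cell_b = purrr::map_dbl(placed, "b"),
      theta = purrr::map_dbl(placed, "theta"),
      nuc_a = purrr::map_dbl(placed, "na"),
      nuc_b = purrr::map_dbl(placed, "nb"),
      class = classes, lambda = lambda)
  })
}

#' Render a cell layout into a Poisson ion-count image stack
#'
#' Every pixel of every channel draws an integer count from a Poisson law
#' whose rate is the background rate plus the contributions of the cells
#' covering that pixel. Nuclear-compartment channels deposit only inside
#' the nucleus ellipse, membrane channels only in a 2-pixel rim inside the
#' cell boundary, cytoplasm channels in the cell minus the nucleus, and
#' `"any"` channels over the whole cell. Ground-truth label masks rasterize
#' the ellipses; where placed ellipses overlap, earlier cells keep their
#' pixels.
#'
#' @param cells Layout tibble from [sample_cell_layout()].
#' @param panel An [imc_panel()].
#' @param roi_size `(width, height)` in micrometres.
#' @param seed Integer seed for the Poisson draw.
#' @param background_lambda Mean background count per pixel.
#' @param pixel_size Micrometres per pixel (default 1).
#' @param roi_id,condition Identifiers stored in the stack and truth table.
#' @return An object of class `synthetic_roi`: a list with elements
#'   `stack` ([imc_stack()]), `truth_nuclei` and `truth_cells`
#'   ([label_mask()]), `truth_table` (per-cell features with `true_class`),
#'   and `seed`.
#' @export
render_roi <- function(cells, panel, roi_size = c(500, 500), seed = 1,
                       background_lambda = 0.2, pixel_size = 1,
                       roi_id = "roi", condition = NA_character_) {
  ps <- pixel_size
  W <- as.integer(round(roi_size[1] / ps))
  H <- as.integer(round(roi_size[2] / ps))
  C <- nrow(panel)
  if (nrow(cells) > 0) {
    rmax <- pmax(cells$cell_a, cells$cell_b)
    abort_if(any(cells$x - rmax < 0 | cells$x + rmax > roi_size[1] |
                   cells$y - rmax < 0 | cells$y + rmax > roi_size[2]),
             "cells must fit inside the ROI")
  }
  cell_lab <- matrix(0L, H, W)
  nuc_lab <- matrix(0L, H, W)
  regions <- vector("list", nrow(cells))   # per-cell compartment pixels
  keep <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    own <- ellipse_pixels(cl$x, cl$y, cl$cell_a, cl$cell_b, cl$theta,
                          H, W, ps)
    own <- own[cell_lab[own] == 0L]
    if (length(own) == 0) next
    npx <- ellipse_pixels(cl$x, cl$y, cl$nuc_a, cl$nuc_b, cl$theta,
                          H, W, ps)
    npx <- intersect(npx, own)
    if (length(npx) == 0) next
    # 2-pixel rim inside the cell boundary: outside the shrunken ellipse
    sa <- max(cl$cell_a - 2 * ps, 0.5 * ps)
    sb <- max(cl$cell_b - 2 * ps, 0.5 * ps)
    ci <- (own - 1L) %/% H + 1L
    ri <- (own - 1L) %% H + 1L
    dx <- (ci - 1) * ps - cl$x
    dy <- (ri - 1) * ps - cl$y
    u <- (dx * cos(cl$theta) + dy * sin(cl$theta)) / sa
    v <- (-dx * sin(cl$theta) + dy * cos(cl$theta)) / sb
    rim <- own[u * u + v * v > 1]
    cell_lab[own] <- i
    nuc_lab[npx] <- i
    regions[[i]] <- list(nucleus = npx, cytoplasm = setdiff(own, npx),
                         membrane = rim, any = own)
    keep[i] <- TRUE
  }
  bad <- setdiff(unique(panel$compartment),
                 c("nucleus", "cytoplasm", "membrane", "any"))
  abort_if(length(bad) > 0, "unknown compartment class: %s",
           paste(bad, collapse = ", "))
  rates <- array(background_lambda, dim = c(H, W, C))
  plane <- as.integer(H) * as.integer(W)
  for (k in seq_len(C)) {
    comp <- panel$compartment[k]
    mk <- panel$marker[k]
    off <- (k - 1L) * plane
    for (i in which(keep)) {
      lam <- cells$lambda[[i]][mk]
      if (is.na(lam) || lam <= 0) next
      px <- regions[[i]][[comp]]
      if (length(px) > 0) rates[px + off] <- rates[px + off] + lam
    }
  }
  counts <- withr::with_seed(seed, stats::rpois(length(rates), rates))
  pixels <- array(as.numeric(counts), dim = c(H, W, C))
  # relabel dropped (fully occluded) cells out, keeping consecutive labels
  kept_ids <- which(keep)
  remap <- integer(nrow(cells))
  remap[kept_ids] <- seq_along(kept_ids)
  cell_lab[cell_lab > 0L] <- remap[cell_lab[cell_lab > 0L]]
  nuc_lab[nuc_lab > 0L] <- remap[nuc_lab[nuc_lab > 0L]]
  stack <- imc_stack(pixels, panel, pixel_size = ps, roi_id = roi_id,
                     condition = condition)
  truth_cells <- label_mask(cell_lab, "cells")
  truth_nuclei <- label_mask(nuc_lab, "nuclei")
  truth <- extract_features(stack, truth_cells, truth_nuclei,
                            condition = condition)
  truth$true_class <- cells$class[kept_ids][truth$cell_id]
  structure(list(stack = stack, truth_nuclei = truth_nuclei,
                 truth_cells = truth_cells, truth_table = truth,
                 seed = seed),
            class = "synthetic_roi")
}

#' @export
print.synthetic_roi <- function(x, ...) {
  cat(sprintf("<synthetic_roi> %s: %d cells\n", x$stack$roi_id,
              nrow(x$truth_table)))
  invisible(x)
}

#' Generate a full multi-condition synthetic experiment
#'
#' One ROI per (condition, replicate), each with its own seed derived from
#' the master seed. The default replicate layout mirrors a typical
#' drug-profiling acquisition: two replicate ROIs for each drug (EGF,
#' etoposide, nocodazole) and a single ROI for each control (nontreated,
#' DMSO), eight ROIs in total.
#'
#' @param profiles Named list of [treatment_profile()] objects.
#' @param replicates Named integer vector: replicate ROIs per condition.
#' @param roi_size `(width, height)` in micrometres.
#' @param master_seed Integer master seed; all per-ROI seeds derive from it.
#' @param panel An [imc_panel()]; defaults to [default_panel()].
#' @return Named list of `synthetic_roi` objects
#'   (`<condition>_r<replicate>`).
#' @export
generate_experiment <- function(profiles = default_profiles(),
                                replicates = c(nontreated = 1, DMSO = 1,
                                               EGF = 2, etoposide = 2,
                                               nocodazole = 2),
                                roi_size = c(500, 500), master_seed = 1,
                                panel = default_panel()) {
  abort_if(any(replicates < 1), "replicate counts must be >= 1")
  missing <- setdiff(names(replicates), names(profiles))
  abort_if(length(missing) > 0,
           "conditions in replicates but not in profiles: %s",
           paste(missing, collapse = ", "))
  out <- list()
  for (cond in names(replicates)) {
    for (rep_i in seq_len(replicates[[cond]])) {
      roi_id <- sprintf("%s_r%d", cond, rep_i)
      layout <- sample_cell_layout(
        profiles[[cond]], roi_size,
        seed = derive_seed(master_seed, "layout", roi_id))
      out[[roi_id]] <- render_roi(
        layout, panel, roi_size,
        seed = derive_seed(master_seed, "render", roi_id),
        background_lambda = profiles[[cond]]$background_lambda,
        roi_id = roi_id, condition = cond)
    }
  }
  out
}
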