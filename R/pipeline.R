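# Config-driven orchestration: simulate -> segment -> quantify -> zscore
# -> stats -> embed -> classify -> similarity, with per-stage seeds fanned
# out from one master seed and a JSON run manifest.

.config_schema <- list(
  version = TRUE, seed = TRUE, output_dir = TRUE, stages = TRUE,
  save_images = TRUE,
  simulate = c("roi_size", "replicates"),
  segmentation = c("nuclear_channel", "cyto_channel", "smooth_sigma",
                   "min_diameter", "max_diameter", "declump"),
  zscore = c("channels", "clip_percentile"),
  stats = c("channels", "reference_conditions", "method"),
  tsne = c("perplexity", "max_iter", "sample_size"),
  classifier = c("features", "n_rounds", "folds"),
  similarity = c("population", "parameters", "cross_parameters", "cutoff")
)

.all_stages <- c("simulate", "segment", "quantify", "zscore", "stats",
                 "embed", "classify", "similarity")

#' Build a pipeline configuration
#'
#' Validates a (possibly nested) configuration list against the schema;
#' unknown keys are errors. See the package vignette for the full key
#' reference.
#'
#' @param config Named list (e.g. from [read_pipeline_config()]).
#' @return The validated config with class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  unknown <- setdiff(names(config), names(.config_schema))
  abort_if(length(unknown) > 0, "unknown config keys: %s",
           paste(unknown, collapse = ", "))
  for (key in names(config)) {
    allowed <- .config_schema[[key]]
    if (is.character(allowed)) {
      bad <- setdiff(names(config[[key]]), allowed)
      abort_if(length(bad) > 0, "unknown config keys under %s: %s", key,
               paste(bad, collapse = ", "))
    }
  }
  config$version <- config$version %||% 1
  config$seed <- config$seed %||% 1L
  config$stages <- config$stages %||% .all_stages
  bad <- setdiff(config$stages, .all_stages)
  abort_if(length(bad) > 0, "unknown stages: %s", paste(bad, collapse = ", "))
  config$save_images <- isTRUE(config$save_images)
  structure(config, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

# centroid lookup of truth classes for segmented cells; cells whose
# centroid misses every truth object get NA
.truth_class_at <- function(table, roi) {
  tc <- roi$truth_cells
  ps <- roi$stack$pixel_size
  ri <- pmin(pmax(round(table$centroid_y_um / ps) + 1, 1), nrow(tc))
  ci <- pmin(pmax(round(table$centroid_x_um / ps) + 1, 1), ncol(tc))
  lab <- tc[cbind(ri, ci)]
  cls <- rep(NA_character_, nrow(table))
  hit <- lab > 0
  cls[hit] <- roi$truth_table$true_class[match(lab[hit],
                                               roi$truth_table$cell_id)]
  cls
}

#' Run the full profiling pipeline
#'
#' Executes the configured stages in order on a synthetic experiment:
#' image simulation, nucleus/cell segmentation, per-cell quantification,
#' z-score normalization, condition statistics, t-SNE embedding, nuclear
#' phenotype classification (cross-validation, full scoring, mitotic
#' index), and Pearson similarity analysis of the mitotic population.
#' All numeric artifacts and a JSON manifest (config hash, seed,
#' per-stage object counts, artifact checksums) are written to the output
#' directory; re-running with the same config reproduces them
#' bit-for-bit. A failing stage aborts with the stage name; partial
#' outputs are kept alongside a `FAILED` marker file.
#'
#' @param config A [pipeline_config()] (or plain list).
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return Invisibly, a list with the in-memory results of every stage
#'   that ran plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop(
    "no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stages <- config$stages
  res <- list()
  manifest <- list(version = config$version, seed = seed,
                   config_hash = digest::digest(unclass(config)),
                   stages = stages, counts = list(), artifacts = list())
  log_line <- function(...) {
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
  }
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    log_line("stage %s", name)
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("stage %s: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  save_artifact <- function(file) {
    manifest$artifacts[[basename(file)]] <<- digest::digest(file = file)
  }
  panel <- default_panel()

  run_stage("simulate", {
    sim <- config$simulate %||% list()
    replicates <- unlist(sim$replicates %||%
                           c(nontreated = 1, DMSO = 1, EGF = 2,
                             etoposide = 2, nocodazole = 2))
    roi_size <- unlist(sim$roi_size %||% c(500, 500))
    res$rois <- generate_experiment(default_profiles(),
                                     replicates = replicates,
                                     roi_size = roi_size,
                                     master_seed = seed, panel = panel)
    manifest$counts$n_rois <- length(res$rois)
    if (config$save_images) {
      for (roi in res$rois) write_synthetic_roi(roi, file.path(out_dir,
                                                               "images"))
    }
  })

  run_stage("segment", {
    seg <- config$segmentation %||% list()
    params <- segmentation_params(
      nuclear_channel = seg$nuclear_channel %||% "Ir191-DNA",
      cyto_channel = seg$cyto_channel %||% "pan-keratin",
      smooth_sigma = seg$smooth_sigma %||% 1,
      min_diameter = seg$min_diameter %||% 6,
      max_diameter = seg$max_diameter %||% 30,
      declump = seg$declump %||% TRUE)
    for (ch in c(params$nuclear_channel, params$cyto_channel)) {
      abort_if(!ch %in% panel$marker,
               "channel '%s' is not in the panel", ch)
    }
    res$masks <- lapply(res$rois, function(roi) {
      nuc <- segment_nuclei(roi$stack, params)
      list(nuclei = nuc, cells = segment_cells(roi$stack, nuc, params))
    })
  })

  run_stage("quantify", {
    tables <- lapply(names(res$rois), function(id) {
      roi <- res$rois[[id]]
      tb <- extract_features(roi$stack, res$masks[[id]]$cells,
                             res$masks[[id]]$nuclei)
      manifest$counts$cells_per_roi[[id]] <<- list(
        mask = length(mask_labels(res$masks[[id]]$cells)),
        table = nrow(tb))
      tb$true_class <- .truth_class_at(tb, roi)
      tb
    })
    res$table <- dplyr::bind_rows(tables)
    write_cell_table(res$table, file.path(out_dir, "cell_table.csv"))
    save_artifact(file.path(out_dir, "cell_table.csv"))
  })

  run_stage("zscore", {
    zs <- config$zscore %||% list()
    res$table <- zscore_cells(res$table, channels = zs$channels,
                               clip_percentile = zs$clip_percentile %||% 99)
  })

  run_stage("stats", {
    st <- config$stats %||% list()
    channels <- st$channels %||% c("z_pHistone3-S28", "z_pH2A.X-S139",
                                   "z_Ki-67", "z_p53", "z_cyclinD3",
                                   "z_area_um2")
    res$condition_stats <- compare_conditions(
      res$table, channels,
      reference_conditions = st$reference_conditions %||%
        intersect(c("nontreated", "DMSO"), res$table$condition),
      method = st$method %||% "mann_whitney")
    readr::write_csv(res$condition_stats,
                     file.path(out_dir, "condition_stats.csv"),
                     progress = FALSE)
    save_artifact(file.path(out_dir, "condition_stats.csv"))
  })

  run_stage("embed", {
    ts <- config$tsne %||% list()
    tab <- res$table
    n_max <- ts$sample_size %||% 2000L
    if (nrow(tab) > n_max) {
      keep <- withr::with_seed(derive_seed(seed, "tsne-sample"),
                               sample(nrow(tab), n_max))
      tab <- tab[sort(keep), ]
    }
    res$embedding <- tsne_embed(tab, seed = derive_seed(seed, "tsne"),
                                 perplexity = ts$perplexity %||% 30,
                                 max_iter = ts$max_iter %||% 500)
    readr::write_csv(tibble::as_tibble(res$embedding),
                     file.path(out_dir, "tsne.csv"), progress = FALSE)
    save_artifact(file.path(out_dir, "tsne.csv"))
  })

  run_stage("classify", {
    cf <- config$classifier %||% list()
    features <- cf$features %||% c(intensity_columns(res$table),
                                   size_columns())
    labeled <- res$table[!is.na(res$table$true_class), ]
    manifest$counts$n_labeled <- nrow(labeled)
    res$confusion <- cross_validate(labeled, labeled$true_class,
                                     features, folds = cf$folds %||% 5,
                                     n_rounds = cf$n_rounds %||% 50,
                                     seed = derive_seed(seed, "cv"))
    res$model <- train_fast_gentle_boosting(labeled, labeled$true_class,
                                             features,
                                             n_rounds = cf$n_rounds %||% 50)
    res$table <- score_cells(res$model, res$table)
    res$mitotic <- mitotic_index(res$table)
    write_boost_model(res$model, file.path(out_dir, "model.json"))
    readr::write_csv(tidy.confusion_matrix(res$confusion),
                     file.path(out_dir, "confusion.csv"), progress = FALSE)
    readr::write_csv(res$mitotic, file.path(out_dir, "mitotic_index.csv"),
                     progress = FALSE)
    for (f in c("model.json", "confusion.csv", "mitotic_index.csv")) {
      save_artifact(file.path(out_dir, f))
    }
  })

  run_stage("similarity", {
    sm <- config$similarity %||% list()
    population <- sm$population %||% "pHistone3+"
    params <- sm$parameters %||% c(
      "Ir191-DNA", "Ir193-DNA", "pHistone3-S28", "pH2A.X-S139", "Ki-67",
      "p53", "cyclinB1", "cyclinD3", "p4E-BP1", "cPARP", "pan-keratin",
      "CK19", "CD29", "CD81", "CD98", "CD47", "CD49e", "EpCAM",
      size_columns())
    res$similarity <- pearson_matrix(res$table, params,
                                      population = population)
    res$dendrogram <- hierarchical_order(res$similarity)
    cross_params <- sm$cross_parameters %||% c("CD98", "CD29", "EpCAM",
                                               "CD81", "CD47", "CD49e")
    res$cross_similarity <- cross_condition_similarity(
      res$table, cross_params, population = population)
    res$graph <- edge_bundle_graph(res$cross_similarity,
                                    cutoff = sm$cutoff %||% 0.3)
    write_similarity(res$similarity, file.path(out_dir, "similarity.csv"))
    writeLines(res$dendrogram$newick,
               file.path(out_dir, "similarity_dendrogram.nwk"))
    write_similarity(res$cross_similarity,
                     file.path(out_dir, "cross_condition_similarity.csv"))
    write_graph_json(res$graph, file.path(out_dir, "graph.json"))
    write_graph_graphml(res$graph, file.path(out_dir, "graph.graphml"))
    for (f in c("similarity.csv", "similarity_dendrogram.nwk",
                "cross_condition_similarity.csv", "graph.json")) {
      save_artifact(file.path(out_dir, f))
    }
  })

  manifest$counts$n_cells <- if (!is.null(res$table)) nrow(res$table)
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline complete: %s", out_dir)
  invisible(res)
}
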