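# End-to-end experiment orchestration --------------------------------------

#' Experiment configuration
#'
#' Describes one full experiment: knowledge source (either paths to a
#' relations TSV / GMT / optional regulon TSV, or a synthetic configuration
#' — exactly one of the two), data source (modality matrices + labels, or
#' the synthetic cohort), model and training settings, and the stability
#' protocol (number of independent runs, attribution steps, top-N).
#'
#' @param synthetic a [synthetic_config()], or `NULL` when knowledge files
#'   are given.
#' @param knowledge_files named list with `relations`, `genesets`, and
#'   optionally `regulon` paths, or `NULL` when `synthetic` is given.
#' @param data named list with `modalities` (named list of samples x genes
#'   matrices) and `labels`; required with `knowledge_files`, ignored with
#'   `synthetic`.
#' @param n_layers pathway layers retained in the model.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param n_runs independent training runs for the stability analysis.
#' @param attribution_steps path quadrature points for attribution.
#' @param n_top top-N for the Jaccard stability statistic.
#' @param seed base seed; run r uses `seed + r` for its fold split and
#'   model initialization.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = NULL, knowledge_files = NULL,
                              data = NULL, n_layers = 2L,
                              model = model_config(), train = train_config(),
                              n_runs = 5L, attribution_steps = 32L,
                              n_top = 20L, seed = 1L) {
  if (is.null(synthetic) == is.null(knowledge_files)) {
    stop("exactly one of `synthetic` or `knowledge_files` must be supplied")
  }
  if (!is.null(knowledge_files)) {
    stopifnot(all(c("relations", "genesets") %in% names(knowledge_files)))
    for (f in unlist(knowledge_files)) {
      if (!file.exists(f)) stop("knowledge file does not exist: ", f)
    }
    if (is.null(data)) stop("`data` is required with knowledge files")
  }
  structure(
    list(synthetic = synthetic, knowledge_files = knowledge_files,
         data = data, n_layers = as.integer(n_layers), model = model,
         train = train, n_runs = as.integer(n_runs),
         attribution_steps = as.integer(attribution_steps),
         n_top = as.integer(n_top), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Load an experiment configuration from YAML
#'
#' Recognized top-level keys: `synthetic` (fields of [synthetic_config()]),
#' `knowledge_files` (relations/genesets/regulon paths), `n_layers`,
#' `model`, `train`, `n_runs`, `attribution_steps`, `n_top`, `seed`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(
    synthetic = if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic),
    knowledge_files = y$knowledge_files,
    data = NULL,
    n_layers = y$n_layers %||% 2L,
    model = do.call(model_config, y$model %||% list()),
    train = do.call(train_config, y$train %||% list()),
    n_runs = y$n_runs %||% 5L,
    attribution_steps = y$attribution_steps %||% 32L,
    n_top = y$n_top %||% 20L,
    seed = y$seed %||% 1L
  )
}

#' Run a full experiment
#'
#' Executes the pipeline: obtain the knowledge graph (simulate or parse),
#' build masks, then perform `n_runs` independent runs. Run r (seeded
#' `seed + r`) splits the cohort into `train$n_folds` stratified folds,
#' trains one model per fold recording its test AUC, and computes an
#' importance table (gene integrated gradients + pathway-layer conductance)
#' with the first fold's model on that fold's test samples. Importance
#' tables across runs feed a [stability_report()]. All artifacts are
#' written under `out_dir` and listed in `manifest.json` with md5 content
#' hashes, the resolved seeds, and the configuration, so every output is
#' re-derivable.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory.
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "knowledge"
  manifest <- list(config = serialize_config(cfg), seeds = list(), files = list())
  tryCatch({
    if (!is.null(cfg$synthetic)) {
      kg <- simulate_hierarchy(cfg$synthetic)
      paths <- write_knowledge_files(kg, file.path(out_dir, "knowledge"))
      cohort <- simulate_cohort(kg, cfg$synthetic)
      modalities <- cohort$modalities
      labels <- cohort$labels
      truth_path <- file.path(out_dir, "truth.json")
      jsonlite::write_json(
        list(causal_pathways = cohort$truth$causal_pathways,
             causal_genes = cohort$truth$causal_genes),
        truth_path, auto_unbox = FALSE, pretty = TRUE)
      hierarchy <- kg$hierarchy; membership <- kg$membership
      regulon <- if (cfg$model$use_regulatory) kg$regulon
      files <- c(paths, truth = truth_path)
    } else {
      hierarchy <- parse_pathway_relations(cfg$knowledge_files$relations)
      membership <- parse_gene_sets(cfg$knowledge_files$genesets)
      regulon <- if (!is.null(cfg$knowledge_files$regulon)) {
        parse_regulatory_edges(cfg$knowledge_files$regulon)
      }
      modalities <- cfg$data$modalities
      labels <- cfg$data$labels
      files <- character(0)
      cohort <- NULL
    }

    stage <- "masks"
    masks <- build_layer_masks(hierarchy, membership, regulon = regulon,
                               n_layers = cfg$n_layers)
    mask_dir <- file.path(out_dir, "masks")
    write_mask_stack(masks, mask_dir)
    files <- c(files, list.files(mask_dir, full.names = TRUE))

    stage <- "training"
    metrics <- data.frame(run = integer(0), fold = integer(0), auc = numeric(0))
    run_tables <- list()
    for (r in seq_len(cfg$n_runs)) {
      run_seed <- cfg$seed + r
      manifest$seeds[[paste0("run", r)]] <- run_seed
      folds <- stratified_kfold(labels, cfg$train$n_folds, seed = run_seed)
      for (f in seq_along(folds)) {
        tr <- folds[[f]]$train; te <- folds[[f]]$test
        mc <- cfg$model; mc$seed <- run_seed * 1000L + f
        model <- assemble_pnet(masks, mc, modalities = names(modalities))
        tc <- cfg$train; tc$seed <- run_seed * 1000L + f
        xtr <- lapply(modalities, function(m) m[tr, , drop = FALSE])
        xte <- lapply(modalities, function(m) m[te, , drop = FALSE])
        model <- train_model(model, xtr, labels[tr], tc)
        pred <- forward_predict(model, xte)
        metrics <- rbind(metrics, data.frame(
          run = r, fold = f, auc = auc_roc(pred$combined_probability, labels[te])))
        if (f == 1L) {
          stage <- "attribution"
          run_tables[[r]] <- importance_table(
            model, xte, run_id = paste0("run", r),
            steps = cfg$attribution_steps)
          imp_path <- file.path(out_dir, sprintf("importance_run%d.csv", r))
          utils::write.csv(run_tables[[r]], imp_path, row.names = FALSE)
          files <- c(files, imp_path)
          stage <- "training"
        }
      }
    }
    metrics_path <- file.path(out_dir, "fold_metrics.csv")
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
    files <- c(files, metrics_path)

    stage <- "stability"
    report <- NULL
    if (length(run_tables) >= 2) {
      report <- stability_report(run_tables, n_top = cfg$n_top)
      rep_path <- file.path(out_dir, "stability_report.csv")
      write_stability_report(report, rep_path)
      files <- c(files, rep_path)
    }

    manifest$files <- lapply(stats::setNames(nm = unname(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(c(manifest,
                list(metrics = metrics, importance = run_tables,
                     stability = report,
                     truth = if (!is.null(cohort)) cohort$truth)))
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "' (base seed ", cfg$seed,
         "): ", conditionMessage(e), call. = FALSE)
  })
}

# Resolved, fully serialized config (defaults included) for the manifest.
serialize_config <- function(cfg) {
  list(
    synthetic = if (!is.null(cfg$synthetic)) unclass(cfg$synthetic),
    knowledge_files = cfg$knowledge_files,
    n_layers = cfg$n_layers,
    model = unclass(cfg$model),
    train = unclass(cfg$train),
    n_runs = cfg$n_runs,
    attribution_steps = cfg$attribution_steps,
    n_top = cfg$n_top,
    seed = cfg$seed
  )
}
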