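# Planted-signal recovery benchmark ---------------------------------------

# Ancestors of a set of pathway nodes (excluding the nodes themselves).
pathway_ancestors <- function(hierarchy, nodes) {
  parent_of <- split(hierarchy$edges$parent, hierarchy$edges$child)
  out <- character(0)
  frontier <- nodes
  while (length(frontier) > 0) {
    up <- unique(unlist(parent_of[frontier], use.names = FALSE))
    up <- setdiff(up, out)
    out <- c(out, up)
    frontier <- up
  }
  setdiff(out, nodes)
}

#' Planted-signal parameter-recovery benchmark
#'
#' Simulates a cohort whose labels derive from a planted causal gene subset
#' (member genes of a few causal leaf pathways), trains the pathway-guided
#' network in `n_runs` independent runs (distinct fold splits and
#' initializations), and measures whether interpretation recovers the
#' planted structure:
#'
#' * `mean_test_auc` — mean held-out AUC over runs;
#' * `causal_jaccard` — mean Jaccard between each run's top-`n_top`
#'   gene-importance set and the true causal gene set;
#' * `causal_perm_p` — permutation p-value of `causal_jaccard` against the
#'   chance level of uniformly random top sets (hypergeometric null);
#' * `snr_ranksum_p` — one-sided rank-sum p-value that the planted causal
#'   pathways have higher importance SNR across runs than non-planted
#'   pathway nodes;
#' * `stability_jaccard` — mean pairwise top-`n_top` Jaccard of the gene
#'   ranking across runs.
#'
#' @param seed base seed; all randomness derives from it.
#' @param cfg a [synthetic_config()]; the defaults are the benchmark's
#'   study conditions.
#' @param n_runs independent runs (default 5).
#' @param n_layers pathway layers retained (default 2, so each retained
#'   layer has enough nodes for layerwise statistics).
#' @param train a [train_config()]; the default trains full-batch for 300
#'   epochs at learning rate 0.02 with weight decay 0.03 (chosen for
#'   held-out AUC on this genes >> samples regime) and 5-fold splits, one
#'   fold held out per run.
#' @param steps attribution quadrature points.
#' @param n_top top-N for the recovery and stability statistics.
#' @param n_perm permutations for the chance-level test.
#' @return List of class `planted_benchmark` with the measures above plus
#'   `truth`, `metrics` (per-run AUC), `runs` (importance tables) and
#'   `report` (the [stability_report()]).
#' @export
planted_benchmark <- function(seed = 1L, cfg = synthetic_config(seed = seed),
                              n_runs = 5L, n_layers = 2L,
                              train = train_config(n_folds = 5L, epochs = 300L,
                                                   learning_rate = 0.02,
                                                   weight_decay = 0.03),
                              steps = 32L, n_top = 20L, n_perm = 10000L) {
  kg <- simulate_hierarchy(cfg)
  cohort <- simulate_cohort(kg, cfg)
  masks <- build_layer_masks(kg$hierarchy, kg$membership, n_layers = n_layers)

  metrics <- data.frame(run = integer(0), auc = numeric(0))
  run_tables <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed) * 1000L + r
    folds <- stratified_kfold(cohort$labels, train$n_folds, seed = run_seed)
    fold <- folds[[1L + (r - 1L) %% train$n_folds]]
    mc <- model_config(seed = run_seed)
    model <- assemble_pnet(masks, mc, modalities = names(cohort$modalities))
    tc <- train
    tc$seed <- run_seed
    xtr <- lapply(cohort$modalities, function(m) m[fold$train, , drop = FALSE])
    xte <- lapply(cohort$modalities, function(m) m[fold$test, , drop = FALSE])
    model <- train_model(model, xtr, cohort$labels[fold$train], tc)
    pred <- forward_predict(model, xte)
    metrics <- rbind(metrics, data.frame(
      run = r, auc = auc_roc(pred$combined_probability, cohort$labels[fold$test])))
    # attribution on the full cohort, fixed across runs, so across-run SNR
    # reflects run-to-run model variability rather than evaluation-set
    # sampling noise
    run_tables[[r]] <- importance_table(model, cohort$modalities,
                                        run_id = paste0("run", r),
                                        steps = steps)
  }

  causal <- cohort$truth$causal_genes
  genes <- kg$membership$genes
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  tops <- lapply(run_tables, top_n_nodes, n = n_top, layer = "gene")
  causal_jaccard <- mean(vapply(tops, jac, numeric(1), b = causal))

  set.seed(as.integer(seed))
  null_stat <- vapply(seq_len(n_perm), function(i) {
    mean(vapply(seq_len(n_runs), function(r) {
      jac(sample(genes, n_top), causal)
    }, numeric(1)))
  }, numeric(1))
  causal_perm_p <- (1 + sum(null_stat >= causal_jaccard)) / (1 + n_perm)

  report <- stability_report(run_tables, n_top = n_top)
  tab <- report$table
  ptab <- tab[tab$layer != "gene" & is.finite(tab$snr), , drop = FALSE]
  is_planted <- ptab$node_id %in% cohort$truth$causal_pathways
  snr_ranksum_p <- stats::wilcox.test(ptab$snr[is_planted], ptab$snr[!is_planted],
                                      alternative = "greater")$p.value

  structure(
    list(mean_test_auc = mean(metrics$auc),
         causal_jaccard = causal_jaccard,
         causal_perm_p = causal_perm_p,
         snr_ranksum_p = snr_ranksum_p,
         stability_jaccard = report$jaccard_mean,
         truth = cohort$truth, metrics = metrics, runs = run_tables,
         report = report),
    class = "planted_benchmark"
  )
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat(sprintf(paste0(
    "Planted-signal benchmark (%d runs)\n",
    "  mean test AUC          %.3f\n",
    "  top-20 causal Jaccard  %.3f (permutation p = %.3g)\n",
    "  planted SNR rank-sum p %.3g\n",
    "  top-20 gene stability  %.3f\n"),
    nrow(x$metrics), x$mean_test_auc, x$causal_jaccard, x$causal_perm_p,
    x$snr_ranksum_p, x$stability_jaccard))
  invisible(x)
}
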