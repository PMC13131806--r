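# Synthetic knowledge graphs and cohorts -----------------------------------

#' Synthetic study configuration
#'
#' Defaults realize the package's planted-signal benchmark conditions: a
#' depth-3 balanced pathway tree with 49 leaves, 200 genes placed 5 per leaf
#' (every gene at least once), two causal leaf pathways whose ~10 member
#' genes carry a log-odds effect of 1.5 per unit through each of two data
#' modalities, 600 samples, 5% label noise.
#'
#' @param n_genes number of genes.
#' @param n_layers depth of the balanced pathway tree (leaves at layer 1).
#' @param branching children per internal pathway.
#' @param genes_per_leaf gene slots per leaf pathway (overlap allowed).
#' @param n_tfs number of genes designated transcription factors.
#' @param targets_per_tf signed targets per TF.
#' @param n_samples cohort size.
#' @param n_modalities 1 = continuous only, 2 = continuous + binary
#'   (mirroring expression + mutation style inputs).
#' @param causal_pathway_count number of causal leaf pathways.
#' @param effect_size log-odds per causal gene unit.
#' @param label_noise label flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L, n_layers = 3L, branching = 7L,
                             genes_per_leaf = 5L, n_tfs = 10L,
                             targets_per_tf = 10L, n_samples = 600L,
                             n_modalities = 2L, causal_pathway_count = 2L,
                             effect_size = 1.5, label_noise = 0.05,
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_layers >= 1, branching >= 1, genes_per_leaf >= 1,
            n_tfs >= 0, targets_per_tf >= 0, n_samples >= 1,
            n_modalities %in% c(1L, 2L), causal_pathway_count >= 1,
            label_noise >= 0, label_noise < 0.5)
  structure(
    list(n_genes = as.integer(n_genes), n_layers = as.integer(n_layers),
         branching = as.integer(branching),
         genes_per_leaf = as.integer(genes_per_leaf), n_tfs = as.integer(n_tfs),
         targets_per_tf = as.integer(targets_per_tf),
         n_samples = as.integer(n_samples),
         n_modalities = as.integer(n_modalities),
         causal_pathway_count = as.integer(causal_pathway_count),
         effect_size = effect_size, label_noise = label_noise,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a pathway hierarchy, gene membership and regulon
#'
#' Generates a balanced rooted tree of depth `n_layers` (level k holds
#' `branching^(n_layers - k)` pathways; leaves at layer 1), assigns genes to
#' leaves (each leaf draws `genes_per_leaf` genes; every gene is placed at
#' least once, extra slots are drawn uniformly with replacement so overlap
#' is allowed), and designates `n_tfs` genes as transcription factors with
#' `targets_per_tf` signed targets each (signs +/- with equal probability).
#' Reproducible per seed.
#'
#' @param cfg a [synthetic_config()].
#' @return An object of class `synthetic_knowledge`: list with `hierarchy`
#'   ([pathway_hierarchy()]), `membership` ([gene_membership()]), `regulon`
#'   ([regulatory_network()]), `leaves` and `cfg`.
#' @export
simulate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  L <- cfg$n_layers
  n_at <- cfg$branching^(L - seq_len(L)) # level 1..L counts, leaves first
  wid <- max(3L, nchar(as.character(max(n_at))))
  node_id <- function(level, i) sprintf("P%d_%0*d", level, wid, i)
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  nodes <- character(0)
  for (lev in L:1) {
    ids <- node_id(lev, seq_len(n_at[lev]))
    nodes <- c(nodes, ids)
    if (lev < L) {
      parents <- node_id(lev + 1L, ((seq_len(n_at[lev]) - 1L) %/% cfg$branching) + 1L)
      edges <- rbind(edges, data.frame(parent = parents, child = ids,
                                       stringsAsFactors = FALSE))
    }
  }
  hierarchy <- pathway_hierarchy(nodes, edges)
  leaves <- node_id(1L, seq_len(n_at[1L]))

  n_slots <- length(leaves) * cfg$genes_per_leaf
  if (n_slots < cfg$n_genes) {
    stop("infeasible: ", cfg$n_genes, " genes but only ", n_slots,
         " leaf slots (", length(leaves), " leaves x ", cfg$genes_per_leaf, ")")
  }
  gwid <- max(3L, nchar(as.character(cfg$n_genes)))
  genes <- sprintf("g%0*d", gwid, seq_len(cfg$n_genes))
  fill <- c(sample(genes),
            if (n_slots > cfg$n_genes)
              sample(genes, n_slots - cfg$n_genes, replace = TRUE))
  fill <- sample(fill)
  sets <- stats::setNames(
    lapply(seq_along(leaves), function(i) {
      sort(unique(fill[((i - 1L) * cfg$genes_per_leaf + 1L):(i * cfg$genes_per_leaf)]))
    }),
    leaves
  )
  membership <- gene_membership(sets, genes = genes)

  if (cfg$n_tfs > 0 && cfg$targets_per_tf > 0) {
    tfs <- sort(sample(genes, cfg$n_tfs))
    ed <- do.call(rbind, lapply(tfs, function(t) {
      tg <- sample(setdiff(genes, t), min(cfg$targets_per_tf, cfg$n_genes - 1L))
      data.frame(tf = t, target = tg,
                 sign = sample(c(-1L, 1L), length(tg), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    regulon <- regulatory_network(ed)
  } else {
    regulon <- regulatory_network()
  }

  structure(
    list(hierarchy = hierarchy, membership = membership, regulon = regulon,
         leaves = leaves, cfg = cfg),
    class = "synthetic_knowledge"
  )
}

#' Write synthetic knowledge files in their field dialects
#'
#' Emits `relations.tsv` (parent<TAB>child, no header), `sets.gmt` and
#' `regulon.tsv` (header `source target weight`). Output is byte-stable for
#' a given knowledge object.
#'
#' @param kg a `synthetic_knowledge` object.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_knowledge_files <- function(kg, dir) {
  stopifnot(inherits(kg, "synthetic_knowledge"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- file.path(dir, "relations.tsv")
  ed <- kg$hierarchy$edges
  writeLines(paste(ed$parent, ed$child, sep = "\t"), rel)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(vapply(names(kg$membership$sets), function(s) {
    paste(c(s, "synthetic", kg$membership$sets[[s]]), collapse = "\t")
  }, character(1)), gmt)
  reg <- file.path(dir, "regulon.tsv")
  re <- kg$regulon$edges
  writeLines(c("source\ttarget\tweight",
               if (nrow(re) > 0) paste(re$tf, re$target, re$sign, sep = "\t")),
             reg)
  invisible(c(relations = rel, gmt = gmt, regulon = reg))
}

#' Simulate a labeled cohort with planted causal structure
#'
#' Chooses `causal_pathway_count` leaf pathways; their member genes carry
#' effect `beta = effect_size`, all other genes 0. The continuous modality
#' is standard normal per gene; the binary modality is Bernoulli(0.1).
#' Labels are drawn from `logistic(X_cont beta + X_bin beta)` and then
#' flipped with probability `label_noise`.
#'
#' @param kg a `synthetic_knowledge` from [simulate_hierarchy()].
#' @param cfg a [synthetic_config()] (cohort-relevant fields are used).
#' @param seed cohort seed; defaults to `cfg$seed + 1` so knowledge and
#'   cohort draws are decoupled.
#' @return List of class `synthetic_cohort`: `modalities` (named list of
#'   samples x genes matrices), `labels` (0/1), `truth` (list with
#'   `causal_pathways`, `causal_genes`, `beta`, and the class probabilities
#'   `prob` before flipping).
#' @export
simulate_cohort <- function(kg, cfg = kg$cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(kg, "synthetic_knowledge"))
  leaves <- kg$leaves
  if (cfg$causal_pathway_count > length(leaves)) {
    stop("causal_pathway_count exceeds the number of leaf pathways (",
         length(leaves), ")")
  }
  set.seed(as.integer(seed))
  causal_pw <- sort(sample(leaves, cfg$causal_pathway_count))
  causal_genes <- sort(unique(unlist(kg$membership$sets[causal_pw])))
  genes <- kg$membership$genes
  beta <- stats::setNames(rep(0, length(genes)), genes)
  beta[causal_genes] <- cfg$effect_size

  n <- cfg$n_samples
  Xc <- matrix(stats::rnorm(n * length(genes)), n, length(genes),
               dimnames = list(sprintf("s%04d", seq_len(n)), genes))
  modalities <- list(continuous = Xc)
  eta <- drop(Xc %*% beta)
  if (cfg$n_modalities >= 2L) {
    Xb <- matrix(stats::rbinom(n * length(genes), 1, 0.1), n, length(genes),
                 dimnames = dimnames(Xc))
    modalities$binary <- Xb
    eta <- eta + drop(Xb %*% beta)
  }
  prob <- stats::plogis(eta)
  y <- stats::rbinom(n, 1, prob)
  if (cfg$label_noise > 0) {
    flip <- stats::rbinom(n, 1, cfg$label_noise) == 1
    y[flip] <- 1L - y[flip]
  }
  structure(
    list(modalities = modalities, labels = y,
         truth = list(causal_pathways = causal_pw, causal_genes = causal_genes,
                      beta = beta, prob = prob)),
    class = "synthetic_cohort"
  )
}
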