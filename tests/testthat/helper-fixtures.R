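# Shared fixtures built in code.

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# The 4-node example hierarchy: R -> {A, B}, A -> C.
example_hierarchy <- function() {
  parse_pathway_relations(write_lines_tmp(c("R\tA", "R\tB", "A\tC")))
}

# A random rooted DAG with node count <= n_nodes: nodes are ordered and
# edges always point from a higher-index (parent) to a lower-index node, so
# acyclicity holds by construction.
random_dag <- function(n_nodes, edge_prob = 0.25) {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  # ensure every non-top node has at least one parent so the graph is rooted
  edges <- data.frame(parent = ids[pairs[keep, 2]], child = ids[pairs[keep, 1]],
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_nodes - 1L)) {
    if (!(ids[i] %in% edges$child)) {
      cand <- (i + 1L):n_nodes
      p <- cand[sample.int(length(cand), 1)]
      edges <- rbind(edges, data.frame(parent = ids[p], child = ids[i]))
    }
  }
  pathway_hierarchy(ids, edges)
}

# Random membership attaching each gene to >= 1 pathway of a hierarchy.
random_membership <- function(hierarchy, n_genes) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  sets <- lapply(stats::setNames(nm = hierarchy$nodes), function(p) character(0))
  for (g in genes) {
    pws <- sample(hierarchy$nodes, sample(1:2, 1))
    for (p in pws) sets[[p]] <- c(sets[[p]], g)
  }
  gene_membership(sets[lengths(sets) > 0], genes = genes)
}

# Small synthetic knowledge + cohort used across model/training tests.
toy_world <- function(seed = 7, n_genes = 30, n_samples = 150, effect = 2,
                      n_tfs = 4, noise = 0) {
  cfg <- synthetic_config(n_genes = n_genes, n_layers = 2, branching = 3,
                          genes_per_leaf = 12, n_tfs = n_tfs,
                          targets_per_tf = 5, n_samples = n_samples,
                          effect_size = effect, label_noise = noise,
                          seed = seed)
  kg <- simulate_hierarchy(cfg)
  list(cfg = cfg, kg = kg, cohort = simulate_cohort(kg, cfg),
       masks = build_layer_masks(kg$hierarchy, kg$membership, kg$regulon,
                                 n_layers = 2))
}

# Maximum absolute effective weight over zero-mask positions, across all
# masked layers of a model.
max_offmask_weight <- function(model) {
  vals <- vapply(names(model$par$layers), function(nm) {
    mk <- model$masks[[nm]]
    eff <- binn:::effective_weight(model$par$layers[[nm]]$W, mk,
                                   model$config$signed_mode)
    z <- eff[mk == 0]
    if (length(z) == 0) 0 else max(abs(z))
  }, numeric(1))
  max(vals)
}
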