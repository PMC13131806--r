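# binn — biologically informed sparse neural networks in R

`binn` builds, trains and interprets binary classifiers over gene-level
multi-omic data whose connectivity is dictated by prior biological
knowledge: a hierarchical pathway graph (Reactome-style parent–child
relations plus GMT gene sets) and, optionally, a signed transcription-factor
regulon (CollecTRI-style source/target/weight edge lists). It is aimed at
computational biologists who want predictions they can trace back to genes
and pathways, and who need to know whether those importance calls are
reproducible across retrainings.

## The model

The network is a masked feed-forward architecture:

* a **Gene Input Layer** aggregates each gene's modality channels
  (e.g. mutation + expression) into one gene node;
* an optional **regulatory layer** — a square gene×gene masked layer with a
  +1 self-link per TF and a signed link from each target gene to its TF,
  summed element-wise with the gene representations;
* **pathway layers** whose nodes are pathways and whose connections are
  exactly the child→parent hierarchy edges (genes attach only to their most
  specific pathway level; layer-skipping edges are re-anchored through
  frozen copy-through nodes);
* one **prediction head** per layer, combined by a learned softmax-weighted
  average: the combined logit is `Σ_l ω_l z_l` with `ω ≥ 0, Σ ω = 1`.

Because masks multiply the weights, connections outside the knowledge graph
have identically zero weight and zero gradient — before, during and after
training.

Interpretation uses **integrated gradients** for input channels
(`attr_i = (x_i − x0_i) · mean_path ∂F/∂x_i`, complete with respect to
`F(x) − F(x0)`) and **layer conductance** for hidden pathway nodes, and
reproducibility of importance is quantified across independent runs by
top-N Jaccard stability, per-node SNR (`μ/σ` across runs), layerwise
Z scores, and one-sided normal tail p-values — the statistics used in
published per-gene/per-pathway significance tables.

Degree-matched random-sparse and gene-set (Hallmark-style) first-layer
baselines are included, along with a synthetic generator that emits all
knowledge dialects and cohorts with planted causal structure, so the whole
pipeline is testable end-to-end without external databases.

## Worked example

Simulate a small study (40 genes on a 2-layer hierarchy, 4 TFs, two causal
leaf pathways with effect 2), train 3 independent runs of 4-fold CV with
the regulatory layer on, attribute, and measure stability:

```r
library(binn)

cfg <- experiment_config(
  synthetic = synthetic_config(n_genes = 40, n_layers = 2, branching = 3,
                               genes_per_leaf = 16, n_tfs = 4,
                               targets_per_tf = 6, n_samples = 200,
                               effect_size = 2, seed = 7),
  n_layers = 2,
  model = model_config(use_regulatory = TRUE, seed = 7),
  train = train_config(n_folds = 4, epochs = 60, learning_rate = 0.02,
                       seed = 7),
  n_runs = 3, attribution_steps = 16, n_top = 10, seed = 7)

res <- run_experiment(cfg, "demo_out")
aggregate(auc ~ run, data = res$metrics, FUN = median)
#>   run       auc
#> 1   1 0.8545140
#> 2   2 0.8892045
#> 3   3 0.8433011
print(res$stability)
#> Importance stability: mean top-10 Jaccard = 0.433 over 44 nodes
#>  node_id layer        mu      sigma       snr         z           p
#>     g029  gene 0.3166799 0.03071081 10.311674 2.5394243 0.005551754
#>     g035  gene 0.3323860 0.03321824 10.006129 2.4255649 0.007642290
#>     g019  gene 0.3236152 0.04657421  6.948377 1.2861157 0.099201334
#>     ...
```

Per-run median held-out AUC is ~0.85–0.89; the stability report ranks
nodes by how *consistently* important they are across retrainings: `mu` is
the mean importance, `snr = mu/sigma` its signal-to-noise ratio across the
3 runs, `z` the SNR standardized within the node's layer, and `p` the
one-sided normal tail — the two top genes here are significant at
p < 0.01. `demo_out/` holds the knowledge files, per-fold metrics,
per-run importance tables, the stability report, and a `manifest.json`
with an md5 hash and the resolved seeds for every artifact.

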