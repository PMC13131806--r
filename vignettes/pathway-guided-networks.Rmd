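---
title: "Pathway-guided sparse neural networks: model, interpretation, and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided sparse neural networks: model, interpretation, and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binn)
```

## The model

`binn` builds binary classifiers over multi-modal gene-level data (for
example somatic mutations plus normalized expression) whose connectivity is
dictated by prior biological knowledge rather than learned freely. The
network is a sparse feed-forward architecture assembled from three kinds of
masked affine layers:

* **Gene Input Layer (GIL).** Each gene's modality channels connect only to
  that gene's single node (a block mask), so the first hidden layer holds
  one aggregated representation per gene.
* **Regulatory layer (optional).** A square gene-by-gene layer encoding a
  signed transcription-factor regulon: a `+1` self-link for every TF and a
  signed link from each target gene to its regulating TF. Its output is
  summed element-wise with the GIL output before the pathway layers, so
  gene-to-pathway structure is preserved while transcriptional regulation
  is added. Non-TF output nodes have no incoming connections and therefore
  contribute nothing — the layer degrades gracefully to the identity-free
  case when the regulon is empty.
* **Pathway layers.** Nodes are pathways; a connection exists only where
  the hierarchy has a parent–child edge between adjacent layers. Genes
  connect to their most specific (lowest-layer) pathway memberships only.

Every maskable layer carries an affine **prediction head** producing one
logit, and a learned **weighting layer** combines head logits by a softmax
weighted average, so the combined prediction is a convex combination of
per-layer predictions and shallow layers can influence the outcome
directly. Training minimizes the mean of the per-head binary
cross-entropies plus the combined-head cross-entropy with Adam; because the
masks multiply the weights, positions outside the knowledge graph receive
exactly zero gradient and stay exactly zero forever — this is an algebraic
property, not a numerical one, and the test suite asserts exact zeros after
training.

### Layer assignment and copy-through nodes

Pathway layers are indexed from the leaves: a pathway's layer is its
longest path down to a leaf plus one, so layer 1 holds the most specific
pathways and every hierarchy edge spans at least one layer. Two situations
break the "parent exactly one layer up" pattern and are repaired with
frozen copy-through nodes (identity weight, no bias, no activation):

* an edge that skips layers (parent more than one layer above its child)
  is re-anchored through a chain of copies of the child;
* a gene whose most specific membership sits above layer 1 is carried
  upward by a copy chain from the gene layer to its attachment layer.

When a skip parent itself lies above the retained depth `n_layers`, the
chain is capped at `n_layers` so the child's signal still reaches the top
retained layer (and its head). Copy nodes are pass-through by construction:
they are excluded from activation, dropout keeps them as ordinary nodes,
and their single incoming weight is frozen at 1. With multiple roots the
leaf-anchored layering needs no virtual super-root; roots simply land on
whatever layer their depth implies.

Identifiers are ordered lexicographically within every layer, which makes
masks — and therefore models, given a seed — independent of input file row
order.

### Signed regulatory weights

The regulon stores activation/repression as a sign. Under the default
`signed_mode = "softplus"`, the effective weight of a signed connection is
`sign × softplus(raw)`, so an activating edge can never become repressive
during training and vice versa; `signed_mode = "free"` relaxes this and
uses the sign only to orient the initialization. The softplus
reparameterization is smooth, keeps gradients well-behaved near zero, and
is initialized so effective magnitudes match the fan-in-scaled uniform
scheme used for unsigned layers.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_layers` | 2 | pathway layers retained above the gene layer |
| `activation` | `tanh` | hidden nonlinearity (`relu`, `linear` available) |
| `dropout_rate` | 0.1 | dropout on pathway-layer activations (training only) |
| `signed_mode` | `softplus` | sign-preserving regulatory weights |
| `learning_rate` | 1e-3 | Adam step size (0.02 in the benchmark protocol) |
| `weight_decay` | 0.01 | L2 on trainable effective weights and head weights |
| `steps` | 64 | quadrature points for attribution |
| `n_top` | 20 | top-set size for stability statistics |

Weight decay deserves a comment: gene-level cohorts typically have many
more input channels than samples, and an unregularized network reaches
training AUC 1 while generalizing poorly. The benchmark protocol uses
weight decay 0.03 with 300 full-batch epochs at learning rate 0.02, chosen
by held-out AUC on the synthetic regime (200 genes x 2 modalities,
~480 training samples); biases, frozen copies and the head weighting are
exempt from the penalty.

## Attribution and its guarantees

Input importance uses integrated gradients on the combined logit: the
attribution of channel *i* is `(x_i − baseline_i)` times the path-average
gradient along the straight line from the baseline (all zeros — the
absence/reference level for mutation- and expression-style encodings) to
the sample. The midpoint rule is used; for a linear model one step is
exact, and for smooth models the completeness identity (attributions sum
to `F(x) − F(baseline)`) holds to quadrature accuracy — the suite asserts
a 1% relative tolerance at 128 steps.

Hidden-node importance uses layer conductance: each node receives the
path integral of (gradient of the combined logit with respect to the node)
times (the node's activation increment), accumulated over path intervals.
One caveat follows directly from the architecture: because every layer has
its own prediction head, a deep layer does not separate the input from the
output — earlier heads bypass it. A layer's conductances therefore sum to
the part of the output change that layer mediates, not to the full
`F(x) − F(baseline)`; the gene layer, which every head sits above,
satisfies the full identity and is tested for it. Frozen copy nodes
conduct exactly what their origin conducts once the origin has no other
consumers, which the suite checks symbolically on a small linear build.

Per-sample scores are aggregated as the mean of absolute values by default
(`mean` is available); gene scores sum a gene's modality channels before
aggregation.

## Stability statistics

Interpretation is only useful if it is reproducible across retrainings.
For a collection of independent runs the package reports:

* **Top-N Jaccard stability** — the mean pairwise Jaccard index of the
  top-N node sets across runs (ties broken by score, then identifier, for
  determinism); N defaults to 20.
* **Per-node SNR** — mean over runs divided by the sample standard
  deviation (denominator n−1). Nodes with zero variance are reported as
  missing and excluded from layerwise statistics with a message.
* **Layerwise Z** — the SNR standardized within each layer (mean 0, sample
  sd 1 by construction); genes form their own layer. Layers with fewer
  than two defined SNR values (for example a single-root top layer) abort
  the strict operation and are skipped with a message by the report
  wrapper.
* **Tail p-values** — the one-sided upper tail of the standard normal at
  Z. One-sided is the convention that reproduces published per-node
  significance tables from their printed Z scores; a two-sided convention
  would double them.

## The synthetic study and what it shows

The generator emulates the three knowledge inputs (a balanced rooted
pathway tree emitted in the two-column relations dialect, leaf memberships
as GMT, a signed regulon as a source/target/weight TSV) and a cohort whose
labels derive from a planted causal gene subset: the member genes of a few
causal leaf pathways carry a log-odds effect per unit through a standard
normal continuous modality and a Bernoulli(0.1) binary modality, and
labels are drawn from the logistic model then flipped with a small noise
probability.

The benchmark conditions are 200 genes on a depth-3 tree with branching 7
(49 leaves, 5 gene slots per leaf, every gene placed at least once), two
causal leaves (~10 causal genes), effect 1.5, 600 samples, 5% label noise,
and five independent runs (distinct fold splits and initializations); the
model retains two pathway layers so each retained layer has enough nodes
for layerwise statistics, the single root being dropped. Attribution is
computed on the full cohort, fixed across runs, so that across-run SNR
reflects run-to-run model variability rather than evaluation-set sampling
noise. Recovery is quantified as the mean Jaccard between each run's
top-20 genes and the true causal set (against a permutation null of random
top sets), and as a one-sided rank-sum test that the planted causal
pathways' SNR exceeds the non-planted background. One honest observation
from this design: with per-layer heads the network resolves the signal at
the most specific layer that carries it, so ancestors of causal leaves
stay at background importance — the planted set for the rank-sum is
exactly the causal leaves. A second observation: with only two planted
pathways the exact rank-sum has coarse resolution (achievable p-values are
multiples of `1/choose(n, 2)`), so its p-value moves in steps of a few
thousandths per rank; designs that need finer pathway-level p-values
should plant more causal pathways of smaller size.

What passing does **not** show: the generator draws independent standard
normal expression (no covariance structure, no batch effects), effects act
identically through both modalities, and the tree is balanced — real
pathway graphs are multi-parent DAGs with highly skewed set sizes, and
real cohorts are smaller, noisier and confounded. The synthetic results
validate the machinery (masking, training, attribution, statistics), not
biological claims.

## Numerical choices and degenerate inputs

* Stable softplus (`log1p(exp(−|x|)) + max(x, 0)`) avoids overflow.
* AUC uses midranks, i.e. the Mann–Whitney ½-tie convention; degenerate
  single-class inputs are an error.
* Stratified folds deal shuffled class indices round-robin, so per-fold
  class counts differ from proportionality by at most one; a class smaller
  than k is an error.
* Empty knowledge files parse to empty objects without error; cycles in
  the relation file are reported with an explicit cycle; conflicting signs
  for a duplicated regulon pair are an error, same-sign duplicates
  collapse.
* Genes without any usable pathway membership are dropped with a warning
  (they would be dead inputs); a strict mode turns this into an error.
* Full-batch training is the default — with a fixed seed it makes runs
  bit-reproducible; minibatch shuffling and dropout draw from the seeded
  RNG and are equally reproducible single-threaded.
* Zero-variance importance rows are excluded from layerwise statistics
  rather than propagating infinite SNR.

## Known limitations

* Binary outcomes only; no multi-class or survival heads.
* The regulatory layer's output dimension is the gene set; TF-TF cascades
  deeper than one step are not modeled.
* Conductance decomposition is exact only for mediating layers (see
  above); Shapley-style attributions are out of scope.
* The residual reading of "adding pathway representations to gene
  representations" (a skip connection from genes into higher pathway
  layers) is not implemented; per-layer heads already provide a direct
  path from shallow representations to the prediction.
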