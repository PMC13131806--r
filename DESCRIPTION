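Package: binn
Title: Biologically Informed Sparse Neural Networks with Pathway-Guided
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, train and interpret sparse feed-forward neural networks
    whose connectivity is dictated by a hierarchical pathway graph and an
    optional signed transcription-factor regulon. Parsers for pathway
    parent-child relation tables, GMT gene sets and signed regulon edge
    lists produce layer-wise sparsity masks; the assembled network has a
    gene input layer aggregating multiple data modalities, hierarchical
    pathway layers, per-layer prediction heads combined by a learned
    weighted average, and an optional gene-by-gene regulatory layer.
    Includes gradient-based attribution (integrated gradients and layer
    conductance), importance-stability statistics across repeated runs
    (top-N Jaccard, per-node signal-to-noise ratio, layerwise Z scores and
    tail p-values), a synthetic knowledge-graph and cohort generator with
    planted causal structure, and end-to-end experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
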