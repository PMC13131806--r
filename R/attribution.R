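# Path-integral attribution ------------------------------------------------

# Generic IG core over an arbitrary gradient oracle: grad_fn(P) takes a
# points x d matrix of inputs on the straight baseline->x path and returns
# the gradient of the scalar target at each point. Midpoint quadrature.
ig_core <- function(grad_fn, x, baseline, steps) {
  stopifnot(steps >= 1, length(x) == length(baseline))
  alphas <- (seq_len(steps) - 0.5) / steps
  P <- matrix(baseline, steps, length(x), byrow = TRUE) +
    alphas %o% (x - baseline)
  G <- grad_fn(P)
  (x - baseline) * colMeans(G)
}

# Gradient of the combined logit with respect to the (stacked) input.
combined_logit_input_grad <- function(model, P) {
  cache <- pnet_forward(model, P, training = FALSE)
  dlogits <- matrix(cache$omega, nrow(P), length(cache$omega), byrow = TRUE,
                    dimnames = list(NULL, model$stage_names))
  pnet_backward(model, cache, dlogits, input_grad = TRUE)$dX
}

#' Integrated gradients on the model input
#'
#' Attributes the combined logit F to each input channel as
#' `(x_i - baseline_i)` times the path-average of `dF/dx_i` along the
#' straight line from baseline to x (midpoint quadrature). Completeness —
#' the attributions summing to `F(x) - F(baseline)` — holds exactly for
#' linear models at any step count and to quadrature accuracy otherwise.
#'
#' @param model a `pnet_model`.
#' @param x one sample (vector / 1-row matrix) or a samples x inputs matrix;
#'   a list of modality matrices is also accepted.
#' @param baseline reference input of the same width; default all-zeros
#'   (absence / reference level for mutation- and expression-style
#'   encodings).
#' @param steps path quadrature points (>= 1; default 64).
#' @return samples x inputs matrix of attributions (column names are the
#'   `gene|modality` channel ids).
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 64L) {
  X <- align_input(model, x)
  if (is.null(baseline)) baseline <- rep(0, ncol(X))
  baseline <- as.numeric(baseline)
  stopifnot(length(baseline) == ncol(X), steps >= 1)
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = list(rownames(X), colnames(X)))
  for (i in seq_len(nrow(X))) {
    attr_i <- ig_core(function(P) combined_logit_input_grad(model, P),
                      X[i, ], baseline, as.integer(steps))
    if (!all(is.finite(attr_i))) stop("non-finite gradients in integrated gradients")
    out[i, ] <- attr_i
  }
  out
}

#' Layer conductance for hidden nodes
#'
#' Assigns each node of a hidden layer the integral, along the straight
#' baseline-to-input path, of `dF/dh_j * dh_j/dt` (F = combined logit),
#' computed as a Riemann-Stieltjes sum: gradients at interval midpoints
#' times the node's activation increments over the interval. When the layer
#' separates the input from every prediction head downstream (a cut), node
#' conductances sum to `F(x) - F(baseline)`; with per-layer heads, earlier
#' heads bypass deeper layers, so a deeper layer's conductances decompose
#' only the part of F it mediates.
#'
#' @param model a `pnet_model`.
#' @param x one sample or a samples x inputs matrix (or modality list).
#' @param baseline reference input; default all-zeros.
#' @param layer_name one of the model's stage names (`"gene"`,
#'   `"regulatory"`, `"pathway_1"`, ...).
#' @param steps path intervals (>= 1; default 64).
#' @return samples x nodes matrix of conductances for that layer.
#' @export
layer_conductance <- function(model, x, baseline = NULL, layer_name,
                              steps = 64L) {
  if (!(layer_name %in% model$stage_names)) {
    stop("unknown layer: ", layer_name, " (expected one of ",
         paste(model$stage_names, collapse = ", "), ")")
  }
  X <- align_input(model, x)
  if (is.null(baseline)) baseline <- rep(0, ncol(X))
  baseline <- as.numeric(baseline)
  stopifnot(length(baseline) == ncol(X), steps >= 1)
  steps <- as.integer(steps)
  nodes <- colnames(model$par$layers[[
    if (layer_name == "gene") "gene_input" else layer_name]]$W)
  out <- matrix(NA_real_, nrow(X), length(nodes),
                dimnames = list(rownames(X), nodes))
  mids <- (seq_len(steps) - 0.5) / steps
  edges <- seq(0, 1, length.out = steps + 1L)
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - baseline
    Pe <- matrix(baseline, steps + 1L, ncol(X), byrow = TRUE) + edges %o% d
    He <- pnet_forward(model, Pe, training = FALSE)$h[[layer_name]]
    dH <- He[-1L, , drop = FALSE] - He[-(steps + 1L), , drop = FALSE]
    Pm <- matrix(baseline, steps, ncol(X), byrow = TRUE) + mids %o% d
    cache <- pnet_forward(model, Pm, training = FALSE)
    dlogits <- matrix(cache$omega, steps, length(cache$omega), byrow = TRUE,
                      dimnames = list(NULL, model$stage_names))
    G <- pnet_backward(model, cache, dlogits)$dhidden[[layer_name]]
    out[i, ] <- colSums(G * dH)
  }
  out
}

#' Aggregate per-sample importance scores
#'
#' @param scores samples x nodes matrix of per-sample attributions (from
#'   [integrated_gradients()] or [layer_conductance()]).
#' @param method `"mean_abs"` (default: mean of absolute per-sample scores)
#'   or `"mean"`.
#' @return Named numeric vector, one score per node.
#' @export
aggregate_importance <- function(scores, method = c("mean_abs", "mean")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (nrow(scores) == 0 || ncol(scores) == 0) stop("empty importance input")
  if (method == "mean_abs") colMeans(abs(scores)) else colMeans(scores)
}

#' Per-run importance table for genes and hidden layers
#'
#' Runs integrated gradients on the inputs (summed over a gene's modality
#' channels) and layer conductance on each requested hidden layer, then
#' aggregates across samples.
#'
#' @param model a trained `pnet_model`.
#' @param x evaluation samples (modality list or stacked matrix).
#' @param run_id identifier recorded in the table.
#' @param layers hidden layers to score; default all pathway layers.
#' @param steps path quadrature points.
#' @param method sample aggregation, see [aggregate_importance()].
#' @return A data frame (class `importance_table`) with columns `run_id`,
#'   `node_id`, `layer`, `score`. Gene rows carry layer `"gene"`.
#' @export
importance_table <- function(model, x, run_id = "run1",
                             layers = model$pathway_names, steps = 64L,
                             method = "mean_abs") {
  ig <- integrated_gradients(model, x, steps = steps)
  # sum modality channels per gene before aggregating across samples
  gene_of <- sub("\\|[^|]*$", "", colnames(ig))
  per_gene <- sapply(model$genes, function(g) {
    rowSums(ig[, gene_of == g, drop = FALSE])
  })
  if (is.null(dim(per_gene))) per_gene <- matrix(per_gene, nrow = 1,
                                                 dimnames = list(NULL, model$genes))
  rows <- data.frame(
    run_id = run_id, node_id = model$genes, layer = "gene",
    score = unname(aggregate_importance(per_gene, method)),
    stringsAsFactors = FALSE
  )
  for (ln in layers) {
    cond <- layer_conductance(model, x, layer_name = ln, steps = steps)
    rows <- rbind(rows, data.frame(
      run_id = run_id, node_id = colnames(cond), layer = ln,
      score = unname(aggregate_importance(cond, method)),
      stringsAsFactors = FALSE
    ))
  }
  if (!all(is.finite(rows$score))) stop("non-finite importance scores")
  class(rows) <- c("importance_table", "data.frame")
  rows
}
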