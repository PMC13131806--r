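# Pathway-guided masked network ------------------------------------------

#' Model configuration
#'
#' @param use_regulatory include the signed gene-by-gene regulatory layer
#'   (requires a `regulatory` mask in the stack).
#' @param activation hidden activation: `"tanh"` (default), `"relu"`, or
#'   `"linear"` (mostly for analytic tests).
#' @param dropout_rate dropout on pathway-layer activations during training,
#'   in \[0, 1).
#' @param head_weighting how per-layer head logits are combined: `"softmax"`
#'   (learned weights, normalized to a convex combination).
#' @param signed_mode how signed regulatory connections constrain learning:
#'   `"softplus"` (effective weight = sign x softplus(raw), preserving
#'   activation/repression semantics) or `"free"` (sign used as
#'   initialization only).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(use_regulatory = FALSE, activation = c("tanh", "relu", "linear"),
                         dropout_rate = 0.1, head_weighting = "softmax",
                         signed_mode = c("softplus", "free"), seed = 1L) {
  activation <- match.arg(activation)
  signed_mode <- match.arg(signed_mode)
  head_weighting <- match.arg(head_weighting, "softmax")
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(use_regulatory = use_regulatory, activation = activation,
         dropout_rate = dropout_rate, head_weighting = head_weighting,
         signed_mode = signed_mode, seed = as.integer(seed)),
    class = "model_config"
  )
}

# Effective weight of one masked layer. Zero wherever the mask is zero;
# frozen copy-through positions are exactly 1; signed masks optionally map
# the raw weight through sign x softplus(raw).
effective_weight <- function(W, mask, signed_mode = "softplus") {
  pat <- mask != 0
  frz <- mask_frozen(mask)
  signed <- any(mask < 0)
  E <- if (signed && signed_mode == "softplus") {
    sign(mask) * softplus(W) * pat
  } else {
    W * pat
  }
  if (any(frz)) E[frz] <- 1
  E
}

# d(effective)/d(raw): used to chain gradients back to raw weights.
effective_weight_deriv <- function(W, mask, signed_mode = "softplus") {
  pat <- (mask != 0) * 1
  frz <- mask_frozen(mask)
  signed <- any(mask < 0)
  D <- if (signed && signed_mode == "softplus") {
    sign(mask) * stats::plogis(W) * pat
  } else {
    pat
  }
  if (any(frz)) D[frz] <- 0
  D
}

#' Masked affine map
#'
#' Computes `x %*% effective(weights) + bias` where the effective weight is
#' zero wherever `mask` is zero, fixed at 1 on frozen positions, and (for
#' signed masks under `signed_mode = "softplus"`) equals
#' `sign(mask) * softplus(weights)` elsewhere. The gradient with respect to
#' a raw weight at a zero-mask position is identically zero.
#'
#' @param x samples x in_nodes matrix.
#' @param weights raw weight matrix, same shape as `mask`.
#' @param bias length-`ncol(mask)` bias vector.
#' @param mask connectivity mask with entries in -1/0/+1.
#' @param signed_mode see [model_config()]; `"free"` treats signed entries as
#'   plain trainable weights.
#' @return samples x out_nodes matrix.
#' @export
masked_affine <- function(x, weights, bias, mask, signed_mode = "free") {
  x <- as.matrix(x)
  if (ncol(x) != nrow(mask)) {
    stop("dimension mismatch: input has ", ncol(x), " columns but mask has ",
         nrow(mask), " rows")
  }
  stopifnot(identical(dim(weights), dim(mask)), length(bias) == ncol(mask))
  sweep(x %*% effective_weight(weights, mask, signed_mode), 2, bias, `+`)
}

#' Assemble a pathway-guided network
#'
#' Builds the full model from a mask stack: a Gene Input Layer (GIL)
#' aggregating the per-gene channels of each data modality into one gene
#' node (block mask: the channels of gene g connect only to node g), an
#' optional signed regulatory layer whose output is summed element-wise with
#' the GIL output, the hierarchical pathway layers, one affine prediction
#' head per maskable layer, and a learned weighting over heads (initialized
#' uniform).
#'
#' @param masks a [mask_stack()] from [build_layer_masks()] (or a baseline
#'   generator).
#' @param config a [model_config()].
#' @param modalities character vector of modality names (>= 1).
#' @return An object of class `pnet_model` with untrained parameters.
#' @export
assemble_pnet <- function(masks, config = model_config(),
                          modalities = "modality1") {
  stopifnot(inherits(masks, "mask_stack"), inherits(config, "model_config"))
  if (config$use_regulatory && !("regulatory" %in% masks$layer_names)) {
    stop("use_regulatory = TRUE but the mask stack has no regulatory mask")
  }
  genes <- rownames(masks$masks$pathway_1)
  M <- length(modalities)
  stopifnot(M >= 1)
  input_ids <- as.vector(vapply(modalities, function(m) paste(genes, m, sep = "|"),
                                character(length(genes))))
  gil <- matrix(0, length(input_ids), length(genes),
                dimnames = list(input_ids, genes))
  for (m in seq_len(M)) {
    idx <- (m - 1L) * length(genes) + seq_along(genes)
    gil[cbind(idx, seq_along(genes))] <- 1
  }
  layer_masks <- c(list(gene_input = new_mask(gil)),
                   if (config$use_regulatory) masks$masks["regulatory"],
                   masks$masks[grep("^pathway_", masks$layer_names, value = TRUE)])
  pathway_names <- grep("^pathway_", names(layer_masks), value = TRUE)
  stage_names <- c("gene", if (config$use_regulatory) "regulatory", pathway_names)

  set.seed(config$seed)
  par <- list(layers = list(), heads = list(),
              w_heads = rep(0, length(stage_names)))
  for (nm in names(layer_masks)) {
    mk <- layer_masks[[nm]]
    W <- matrix(0, nrow(mk), ncol(mk), dimnames = dimnames(mk))
    fan_in <- pmax(colSums(mk != 0), 1)
    signed <- any(mk < 0)
    for (j in seq_len(ncol(mk))) {
      nz <- which(mk[, j] != 0)
      if (length(nz) == 0) next
      s <- 1 / sqrt(fan_in[j])
      u <- stats::runif(length(nz), -s, s)
      if (signed && config$signed_mode == "softplus") {
        # raw such that softplus(raw) ~ |u|, keeping effective weights small
        W[nz, j] <- log(expm1(pmax(abs(u), 1e-4)))
      } else {
        W[nz, j] <- ifelse(mk[cbind(nz, j)] < 0 & config$signed_mode == "free",
                           -abs(u), u)
      }
    }
    frz <- mask_frozen(mk)
    if (any(frz)) W[frz] <- 1
    par$layers[[nm]] <- list(W = W, b = rep(0, ncol(mk)))
  }
  for (i in seq_along(stage_names)) {
    nm <- stage_names[i]
    width <- if (nm == "gene") length(genes)
             else if (nm == "regulatory") length(genes)
             else ncol(layer_masks[[nm]])
    s <- 1 / sqrt(max(width, 1))
    par$heads[[nm]] <- list(a = stats::runif(width, -s, s), c = 0)
  }

  structure(
    list(config = config, modalities = modalities, genes = genes,
         masks = layer_masks, pathway_names = pathway_names,
         stage_names = stage_names, par = par),
    class = "pnet_model"
  )
}

#' @export
print.pnet_model <- function(x, ...) {
  cat("Pathway-guided network:", length(x$genes), "genes,",
      length(x$modalities), "modalit(ies),",
      length(x$pathway_names), "pathway layer(s),",
      length(x$stage_names), "prediction heads",
      if (x$config$use_regulatory) "(regulatory layer on)" else "", "\n")
  invisible(x)
}

# Align input to the model's stacked gene|modality column layout. Accepts a
# named list of samples x genes matrices (one per modality) or an already
# stacked matrix with matching column names.
align_input <- function(model, x) {
  genes <- model$genes
  if (is.list(x) && !is.data.frame(x)) {
    if (!all(model$modalities %in% names(x))) {
      stop("input must supply modalities: ",
           paste(model$modalities, collapse = ", "))
    }
    blocks <- lapply(model$modalities, function(m) {
      xm <- as.matrix(x[[m]])
      missing <- setdiff(genes, colnames(xm))
      if (length(missing) > 0) {
        stop("modality ", m, " lacks gene columns: ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      xm[, genes, drop = FALSE]
    })
    out <- do.call(cbind, blocks)
    colnames(out) <- rownames(model$masks$gene_input)
    out
  } else {
    x <- as.matrix(x)
    ids <- rownames(model$masks$gene_input)
    if (is.null(colnames(x))) {
      if (ncol(x) != length(ids)) stop("unnamed input with wrong width")
      colnames(x) <- ids
      x
    } else {
      missing <- setdiff(ids, colnames(x))
      if (length(missing) > 0) {
        stop("input lacks columns: ", paste(utils::head(missing, 5), collapse = ", "))
      }
      x[, ids, drop = FALSE]
    }
  }
}

# Full forward pass with caching for backprop. `training` enables dropout
# (inverted scaling) on pathway-layer activations, drawing from the current
# RNG state.
pnet_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  act <- cfg$activation
  cache <- list(X = X, z = list(), h = list(), drop = list())

  lw <- model$par$layers$gene_input
  z0 <- sweep(X %*% effective_weight(lw$W, model$masks$gene_input, cfg$signed_mode),
              2, lw$b, `+`)
  h0 <- apply_activation(z0, act)
  cache$z$gene <- z0; cache$h$gene <- h0

  if (cfg$use_regulatory) {
    lr <- model$par$layers$regulatory
    zr <- sweep(h0 %*% effective_weight(lr$W, model$masks$regulatory, cfg$signed_mode),
                2, lr$b, `+`)
    hr <- apply_activation(zr, act)
    cache$z$regulatory <- zr; cache$h$regulatory <- hr
    u <- h0 + hr
  } else {
    u <- h0
  }
  cache$u0 <- u

  inp <- u
  for (nm in model$pathway_names) {
    lp <- model$par$layers[[nm]]
    mk <- model$masks[[nm]]
    z <- sweep(inp %*% effective_weight(lp$W, mk, cfg$signed_mode), 2, lp$b, `+`)
    h <- apply_activation(z, act)
    pt <- mask_passthrough(mk)
    if (any(pt)) h[, pt] <- z[, pt]  # copy nodes stay linear
    if (training && cfg$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(length(h), 1, 1 - cfg$dropout_rate) /
                       (1 - cfg$dropout_rate), nrow(h), ncol(h))
      cache$drop[[nm]] <- keep
      h <- h * keep
    }
    cache$z[[nm]] <- z; cache$h[[nm]] <- h
    inp <- h
  }

  H <- length(model$stage_names)
  logits <- matrix(0, nrow(X), H,
                   dimnames = list(NULL, model$stage_names))
  for (nm in model$stage_names) {
    hd <- model$par$heads[[nm]]
    logits[, nm] <- drop(cache$h[[nm]] %*% hd$a) + hd$c
  }
  omega <- softmax(model$par$w_heads)
  combined <- drop(logits %*% omega)
  cache$logits <- logits; cache$omega <- omega; cache$combined <- combined
  cache
}

# Backward pass. `dlogits` is the samples x heads matrix of the derivative
# of the scalar objective with respect to each head logit. Returns gradients
# for all layer/head parameters, the total derivative with respect to each
# stage's activation (`dhidden`), and optionally the input gradient.
pnet_backward <- function(model, cache, dlogits, input_grad = FALSE) {
  cfg <- model$config
  act <- cfg$activation
  grads <- list(layers = list(), heads = list(),
                w_heads = rep(0, length(model$par$w_heads)))
  dh <- lapply(cache$h, function(h) array(0, dim = dim(h)))

  for (nm in model$stage_names) {
    g <- dlogits[, nm]
    hd <- model$par$heads[[nm]]
    grads$heads[[nm]] <- list(a = drop(crossprod(cache$h[[nm]], g)), c = sum(g))
    dh[[nm]] <- dh[[nm]] + outer(g, hd$a)
  }

  du_next <- NULL
  for (nm in rev(model$pathway_names)) {
    d <- dh[[nm]]
    if (!is.null(du_next)) d <- d + du_next
    if (!is.null(cache$drop[[nm]])) d <- d * cache$drop[[nm]]
    mk <- model$masks[[nm]]
    pt <- mask_passthrough(mk)
    deriv <- activation_deriv(cache$z[[nm]], cache$h[[nm]], act)
    if (any(pt)) deriv[, pt] <- 1
    dz <- d * deriv
    lp <- model$par$layers[[nm]]
    inp <- if (nm == model$pathway_names[1]) cache$u0
           else cache$h[[model$pathway_names[match(nm, model$pathway_names) - 1L]]]
    grads$layers[[nm]] <- list(
      W = crossprod(inp, dz) * effective_weight_deriv(lp$W, mk, cfg$signed_mode),
      b = colSums(dz) * ifelse(pt, 0, 1)
    )
    du_next <- tcrossprod(dz, effective_weight(lp$W, mk, cfg$signed_mode))
  }
  du0 <- if (is.null(du_next)) array(0, dim = dim(cache$u0)) else du_next

  dh0 <- dh$gene + du0
  if (cfg$use_regulatory) {
    dhr <- dh$regulatory + du0
    mk <- model$masks$regulatory
    deriv <- activation_deriv(cache$z$regulatory, cache$h$regulatory, act)
    dzr <- dhr * deriv
    lr <- model$par$layers$regulatory
    grads$layers$regulatory <- list(
      W = crossprod(cache$h$gene, dzr) *
        effective_weight_deriv(lr$W, mk, cfg$signed_mode),
      b = colSums(dzr)
    )
    dh0 <- dh0 + tcrossprod(dzr, effective_weight(lr$W, mk, cfg$signed_mode))
    dh$regulatory <- dhr
  }
  dh$gene <- dh0

  mk <- model$masks$gene_input
  deriv <- activation_deriv(cache$z$gene, cache$h$gene, act)
  dz0 <- dh0 * deriv
  lg <- model$par$layers$gene_input
  grads$layers$gene_input <- list(
    W = crossprod(cache$X, dz0) * effective_weight_deriv(lg$W, mk, cfg$signed_mode),
    b = colSums(dz0)
  )
  dX <- if (input_grad) {
    tcrossprod(dz0, effective_weight(lg$W, mk, cfg$signed_mode))
  } else NULL

  # order layer grads to match the parameter list
  grads$layers <- grads$layers[names(model$par$layers)]
  grads$heads <- grads$heads[names(model$par$heads)]
  list(grads = grads, dX = dX, dhidden = dh)
}

#' Forward prediction
#'
#' Evaluates the model in inference mode (no dropout) and returns per-head
#' logits, the softmax-weighted combined logit, and the combined probability
#' through a logistic link.
#'
#' @param model a trained or untrained `pnet_model`.
#' @param x input: named list of samples x genes modality matrices, or a
#'   pre-stacked matrix.
#' @return A list of class `batch_prediction` with `per_layer_logits`
#'   (samples x heads), `head_weights`, `combined_logit` and
#'   `combined_probability`.
#' @export
forward_predict <- function(model, x) {
  X <- align_input(model, x)
  cache <- pnet_forward(model, X, training = FALSE)
  structure(
    list(per_layer_logits = cache$logits,
         head_weights = cache$omega,
         combined_logit = cache$combined,
         combined_probability = stats::plogis(cache$combined)),
    class = "batch_prediction"
  )
}

# Hidden activations in inference mode, for attribution.
hidden_activations <- function(model, X) {
  pnet_forward(model, X, training = FALSE)$h
}
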