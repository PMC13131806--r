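# Training and evaluation --------------------------------------------------

#' Training configuration
#'
#' @param n_folds folds for cross-validation (>= 2).
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size; `NULL` (default) trains full-batch,
#'   which keeps runs exactly reproducible with the fewest moving parts.
#' @param class_weighting weight each sample inversely to its class
#'   prevalence in the cross-entropy losses.
#' @param weight_decay L2 penalty on trainable layer and head weights
#'   (biases, frozen copy-through connections and the head weighting are
#'   exempt). The default 0.01 counteracts the overfitting a
#'   genes-much-greater-than-samples cohort invites.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement) when a validation set is supplied to [train_model()].
#' @param seed integer seed controlling shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_folds = 10L, epochs = 100L, learning_rate = 1e-3,
                         batch_size = NULL, class_weighting = FALSE,
                         weight_decay = 0.01, patience = 10L, seed = 1L) {
  stopifnot(n_folds >= 2, epochs >= 0, learning_rate > 0, weight_decay >= 0)
  structure(
    list(n_folds = as.integer(n_folds), epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = batch_size,
         class_weighting = class_weighting, weight_decay = weight_decay,
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Stratified k-fold split
#'
#' Partitions sample indices into k folds preserving the class balance:
#' within each class, shuffled indices are dealt round-robin, so per-fold
#' class counts differ by at most one sample from proportionality.
#'
#' @param labels binary (0/1) label vector.
#' @param k number of folds (>= 2, and at most the size of the smaller class).
#' @param seed integer seed.
#' @return List of k elements, each `list(train = idx, test = idx)`; the
#'   test sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), k >= 2)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < k)) {
    stop("each class needs at least k = ", k, " members (have ",
         paste(tab, collapse = "/"), ")")
  }
  set.seed(as.integer(seed))
  fold_of <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# Per-sample BCE weights: 1, or inverse class prevalence normalized to mean 1.
sample_weights <- function(y, class_weighting) {
  if (!class_weighting) return(rep(1, length(y)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  w
}

# Loss (mean of per-head BCEs + combined BCE, sample-weighted, plus an L2
# penalty on trainable effective weights) and its gradients for one batch.
# Uses one forward + one backward pass.
pnet_loss_grads <- function(model, X, y, wts, weight_decay = 0) {
  cache <- pnet_forward(model, X, training = TRUE)
  n <- nrow(X)
  H <- length(model$stage_names)
  p_heads <- stats::plogis(cache$logits)
  p_comb <- stats::plogis(cache$combined)
  eps <- 1e-12
  bce <- function(p) -mean(wts * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  loss <- mean(apply(p_heads, 2, bce)) + bce(p_comb)

  g_comb <- wts * (p_comb - y) / n
  dlogits <- sweep(p_heads - y, 1, wts / (n * H), `*`) + outer(g_comb, cache$omega)
  dimnames(dlogits) <- list(NULL, model$stage_names)
  bk <- pnet_backward(model, cache, dlogits)

  d_omega <- drop(crossprod(cache$logits, g_comb))
  omega <- cache$omega
  bk$grads$w_heads <- unname(omega * (d_omega - sum(d_omega * omega)))

  if (weight_decay > 0) {
    mask_of <- function(nm) if (nm == "gene") "gene_input" else nm
    for (nm in names(bk$grads$layers)) {
      mk <- model$masks[[nm]]
      W <- model$par$layers[[nm]]$W
      eff <- effective_weight(W, mk, model$config$signed_mode)
      eff[mask_frozen(mk)] <- 0
      loss <- loss + 0.5 * weight_decay * sum(eff^2)
      bk$grads$layers[[nm]]$W <- bk$grads$layers[[nm]]$W +
        weight_decay * eff * effective_weight_deriv(W, mk, model$config$signed_mode)
    }
    for (nm in names(bk$grads$heads)) {
      a <- model$par$heads[[nm]]$a
      loss <- loss + 0.5 * weight_decay * sum(a^2)
      bk$grads$heads[[nm]]$a <- bk$grads$heads[[nm]]$a + weight_decay * a
    }
  }
  list(loss = loss, grads = bk$grads)
}

adam_init <- function(par) {
  list(m = map_leaves(par, function(x) x * 0),
       v = map_leaves(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_leaves2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_leaves2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- map_leaves2(state$m, state$v,
                     function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  par <- map_leaves2(par, upd, `-`)
  list(par = par, state = state)
}

#' Train a pathway-guided network
#'
#' Minimizes the mean of the per-head binary cross-entropies plus the
#' combined-prediction cross-entropy with Adam. Masked-out connections never
#' receive gradient, so the sparsity pattern is preserved exactly at every
#' step. With `validation`, training stops early after
#' `cfg$patience` epochs without validation-loss improvement and the best
#' parameters are restored.
#'
#' @param model a `pnet_model` from [assemble_pnet()].
#' @param x training input (list of modality matrices or stacked matrix).
#' @param y binary label vector.
#' @param cfg a [train_config()].
#' @param validation optional `list(x = ..., y = ...)` held-out set.
#' @return The trained model, with a `history` element (data frame of epoch,
#'   train loss and optional validation loss).
#' @export
train_model <- function(model, x, y, cfg = train_config(), validation = NULL) {
  X <- align_input(model, x)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  wts <- sample_weights(y, cfg$class_weighting)
  Xval <- if (!is.null(validation)) align_input(model, validation$x)
  state <- adam_init(model$par)
  set.seed(cfg$seed)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, par = model$par, epoch = 0L)
  bs <- cfg$batch_size %||% nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (bs < nrow(X)) sample.int(nrow(X)) else seq_len(nrow(X))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, nrow(X), by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nrow(X))]
      lg <- pnet_loss_grads(model, X[idx, , drop = FALSE], y[idx], wts[idx],
                            weight_decay = cfg$weight_decay)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", ep, " (batch starting ", start,
             "); gradient norm ",
             signif(sqrt(reduce_leaves(lg$grads, function(g) sum(g^2))), 4))
      }
      st <- adam_step(model$par, lg$grads, state, cfg$learning_rate)
      model$par <- st$par
      state <- st$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      pv <- stats::plogis(pnet_forward(model, Xval, training = FALSE)$combined)
      eps <- 1e-12
      yv <- as.numeric(validation$y)
      val_loss <- -mean(yv * log(pv + eps) + (1 - yv) * log(1 - pv + eps))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, par = model$par, epoch = ep)
      } else if (ep - best$epoch >= cfg$patience) {
        history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                             val_loss = val_loss))
        model$par <- best$par
        model$history <- history
        return(model)
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         val_loss = val_loss))
  }
  if (!is.null(validation) && is.finite(best$loss)) model$par <- best$par
  model$history <- history
  model
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 P(tie)` via midranks, so ties follow the
#' 1/2-tie convention.
#'
#' @param scores numeric prediction scores.
#' @param labels binary (0/1) labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
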