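#' @keywords internal
"_PACKAGE"

# Numerically stable softplus: log(1 + exp(x)).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Activation functions keyed by name; derivative is expressed in terms of the
# pre-activation z (relu, linear) or the activation h (tanh), whichever is
# cheaper to reuse from the forward cache.
apply_activation <- function(z, activation) {
  switch(activation,
    tanh = tanh(z),
    relu = pmax(z, 0),
    linear = z,
    stop("unknown activation: ", activation)
  )
}

activation_deriv <- function(z, h, activation) {
  switch(activation,
    tanh = 1 - h * h,
    relu = (z > 0) * 1,
    linear = array(1, dim = dim(z)),
    stop("unknown activation: ", activation)
  )
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Recursively apply f to matching numeric leaves of two same-shaped lists.
map_leaves2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) map_leaves2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

map_leaves <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, map_leaves, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

# Sum of f over numeric leaves (used for diagnostics).
reduce_leaves <- function(a, f) {
  if (is.list(a)) sum(vapply(a, reduce_leaves, numeric(1), f = f)) else f(a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
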