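# A tiny linear model: combined logit is an exact linear map of the input,
# so integrated gradients have a closed form w_i * x_i at any step count.
linear_toy <- function() {
  h <- parse_pathway_relations(write_lines_tmp("TOP\tP"))
  s <- build_layer_masks(h, gene_membership(list(P = c("gA", "gB"))), n_layers = 1)
  model <- assemble_pnet(s, model_config(activation = "linear", seed = 1),
                         modalities = "m")
  model$par$layers$gene_input$W[model$masks$gene_input != 0] <- c(2, -3)
  model$par$layers$pathway_1$W[model$masks$pathway_1 != 0] <- c(1, 1)
  model$par$heads$gene$a <- c(0.5, 0.25); model$par$heads$gene$c <- 1
  model$par$heads$pathway_1$a <- 2; model$par$heads$pathway_1$c <- -1
  model$par$w_heads <- c(0, 0)
  model
}

test_that("the quadrature core reproduces closed-form path integrals", {
  # linear gradient: exact at one step
  attr1 <- binn:::ig_core(function(P) matrix(c(3, -2), nrow(P), 2, byrow = TRUE),
                          x = c(2, 5), baseline = c(0, 0), steps = 1)
  expect_equal(attr1, c(6, -10))
  # F(x) = x^2 at x = 2, baseline 0: integral of 2t*2 dt * 2 -> 4
  for (steps in c(4, 64, 512)) {
    a <- binn:::ig_core(function(P) 2 * P, x = 2, baseline = 0, steps = steps)
    expect_equal(a, 4, tolerance = 1e-3)
  }
  # midpoint quadrature error shrinks with steps
  err <- vapply(c(2, 8, 32), function(s) {
    abs(binn:::ig_core(function(P) 3 * P^2, x = 1, baseline = 0, steps = s) - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("integrated gradients are exact on linear models at one step", {
  model <- linear_toy()
  x <- matrix(c(1.5, -2), 1, 2, dimnames = list(NULL, c("gA|m", "gB|m")))
  ig <- integrated_gradients(model, x, steps = 1)
  # effective input weights: w = omega_gene*(W0 a_g) + omega_p*(W0 W1 a_p)
  w_eff <- 0.5 * (c(2, -3) * c(0.5, 0.25)) + 0.5 * (c(2, -3) * 2)
  expect_equal(unname(drop(ig)), unname(w_eff * drop(x)))
  # completeness, exactly
  F1 <- forward_predict(model, x)$combined_logit
  x0 <- x; x0[] <- 0
  F0 <- forward_predict(model, x0)$combined_logit
  expect_equal(sum(ig), F1 - F0)
  # x = baseline -> all zero
  ig0 <- integrated_gradients(model, x0, steps = 4)
  expect_equal(unname(drop(ig0)), c(0, 0))
})

test_that("integrated gradients satisfy completeness on nonlinear models", {
  w <- toy_world()
  set.seed(21)
  for (i in 1:5) {
    model <- assemble_pnet(w$masks,
                           model_config(use_regulatory = (i %% 2 == 0), seed = i),
                           modalities = names(w$cohort$modalities))
    x <- lapply(w$cohort$modalities, function(m) m[i, , drop = FALSE])
    ig <- integrated_gradients(model, x, steps = 128)
    F1 <- forward_predict(model, x)$combined_logit
    x0 <- lapply(x, function(m) m * 0)
    F0 <- forward_predict(model, x0)$combined_logit
    expect_lt(abs(sum(ig) - (F1 - F0)), 0.01 * abs(F1 - F0) + 1e-6)
  }
})

test_that("attributions of fully masked-out inputs are exactly zero", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(seed = 3),
                         modalities = names(w$cohort$modalities))
  # cut every connection leaving one gene's channels
  g <- model$genes[5]
  model$masks$gene_input[paste(g, names(w$cohort$modalities), sep = "|"), ] <- 0
  x <- lapply(w$cohort$modalities, function(m) m[1:3, , drop = FALSE])
  ig <- integrated_gradients(model, x, steps = 8)
  expect_true(all(ig[, paste(g, names(w$cohort$modalities), sep = "|")] == 0))
})

test_that("layer conductance decomposes the output of a mediating layer", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(seed = 6),
                         modalities = names(w$cohort$modalities))
  x <- lapply(w$cohort$modalities, function(m) m[1:3, , drop = FALSE])
  F1 <- forward_predict(model, x)$combined_logit
  x0 <- lapply(x, function(m) m * 0)
  F0 <- forward_predict(model, x0)$combined_logit
  # the gene stage mediates every head, so its conductances are complete
  cond <- layer_conductance(model, x, layer_name = "gene", steps = 128)
  expect_equal(unname(rowSums(cond)), unname(F1 - F0), tolerance = 1e-3)
  expect_error(layer_conductance(model, x, layer_name = "nope", steps = 4),
               "unknown layer")
})

test_that("two-layer linear conductances match the hand chain-rule decomposition", {
  model <- linear_toy()
  x <- matrix(c(2, 1), 1, 2, dimnames = list(NULL, c("gA|m", "gB|m")))
  cond <- layer_conductance(model, x, layer_name = "gene", steps = 1)
  # gene node h_j = W0_j x_j; dF/dh_j = omega_g a_gj + omega_p W1_j a_p
  h <- c(2 * 2, -3 * 1)
  dF <- 0.5 * c(0.5, 0.25) + 0.5 * c(1, 1) * 2
  expect_equal(unname(drop(cond)), unname(dF * h))
  # single linear pathway node: conductance equals total IG
  condp <- layer_conductance(model, x, layer_name = "pathway_1", steps = 1)
  ig <- integrated_gradients(model, x, steps = 1)
  # pathway head carries omega_p of F; gene head bypasses, so compare the
  # mediated share only
  expect_equal(unname(drop(condp)), 0.5 * 2 * sum(h))
  expect_gt(sum(ig), sum(condp)) # bypass share is visible
})

test_that("frozen copy-through nodes conduct exactly what they copy", {
  # B is carried from layer 1 to layer 2 by a frozen copy; with the gene and
  # copy heads silenced, the copy's conductance equals its origin's
  h <- parse_pathway_relations(write_lines_tmp(c("R\tA", "R\tB", "A\tC")))
  s <- build_layer_masks(h, gene_membership(list(C = "g1", B = "g2")), n_layers = 2)
  model <- assemble_pnet(s, model_config(activation = "linear", seed = 2),
                         modalities = "m")
  x <- matrix(c(0.7, -1.2), 1, 2, dimnames = list(NULL, c("g1|m", "g2|m")))
  c1 <- layer_conductance(model, x, layer_name = "pathway_1", steps = 32)
  c2 <- layer_conductance(model, x, layer_name = "pathway_2", steps = 32)
  # B has no trainable consumer beyond its frozen copy; only the heads read
  # them. Scale head readouts identically so the flows match.
  model$par$heads$pathway_1$a[] <- 0
  model$par$heads$pathway_2$a[] <- 0
  model$par$heads$pathway_1$a[colnames(c1) == "B"] <- 1
  model$par$heads$pathway_2$a[colnames(c2) == "B.copy2"] <- 1
  c1 <- layer_conductance(model, x, layer_name = "pathway_1", steps = 32)
  c2 <- layer_conductance(model, x, layer_name = "pathway_2", steps = 32)
  expect_equal(unname(c2[, "B.copy2"]), unname(c1[, "B"]), tolerance = 1e-10)
})

test_that("importance aggregation follows the requested rule", {
  m <- matrix(c(1, -1, 1, 2, 3, 4), 2, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(aggregate_importance(m, "mean_abs"), c(a = 1, b = 1.5, c = 3.5))
  expect_equal(aggregate_importance(m, "mean"), c(a = 0, b = 1.5, c = 3.5))
  expect_equal(aggregate_importance(matrix(c(1, 2, 3), 3, 1,
                                           dimnames = list(NULL, "a"))),
               c(a = 2))
  one <- matrix(-4, 1, 1, dimnames = list(NULL, "a"))
  expect_equal(aggregate_importance(one, "mean_abs"), c(a = 4))
  expect_error(aggregate_importance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("importance tables combine gene IG with pathway conductance", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(seed = 3),
                         modalities = names(w$cohort$modalities))
  x <- lapply(w$cohort$modalities, function(m) m[1:4, , drop = FALSE])
  imp <- importance_table(model, x, run_id = "r1", steps = 8)
  expect_s3_class(imp, "importance_table")
  expect_setequal(unique(imp$layer), c("gene", "pathway_1", "pathway_2"))
  expect_identical(sum(imp$layer == "gene"), length(model$genes))
  expect_true(all(is.finite(imp$score)))
  expect_identical(anyDuplicated(imp[, c("node_id", "layer")]), 0L)
})
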