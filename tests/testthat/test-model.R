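test_that("masked_affine applies mask, frozen and signed semantics", {
  mk <- binn:::new_mask(matrix(c(1, 1, 0, 1), 2, 2,
                               dimnames = list(c("a", "b"), c("u", "v"))))
  W <- matrix(c(3, 7, 5, 11), 2, 2)
  out <- masked_affine(matrix(c(1, 2), 1, 2), W, c(0, 0), mk)
  expect_equal(drop(out), c(u = 17, v = 22))

  # all-zero mask: bias broadcast
  z <- binn:::new_mask(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("u", "v"))))
  out0 <- masked_affine(matrix(rnorm(6), 3, 2), W, c(1, -2), z)
  expect_equal(unname(out0), matrix(c(1, 1, 1, -2, -2, -2), 3, 2))

  # identity mask and weights: identity map
  id <- binn:::new_mask(diag(2) + 0 * diag(2) |> `dimnames<-`(list(c("a", "b"), c("a", "b"))))
  x <- matrix(rnorm(8), 4, 2)
  expect_equal(unname(masked_affine(x, diag(2), c(0, 0), id)), x)

  expect_error(masked_affine(matrix(0, 1, 3), W, c(0, 0), mk), "dimension")

  # signed mask under softplus: effective weight is sign * softplus(raw)
  sm <- binn:::new_mask(matrix(c(1, -1), 1, 2,
                               dimnames = list("a", c("u", "v"))))
  outs <- masked_affine(matrix(2, 1, 1), matrix(c(0.3, 0.3), 1, 2), c(0, 0),
                        sm, signed_mode = "softplus")
  sp <- log(1 + exp(0.3))
  expect_equal(drop(outs), c(u = 2 * sp, v = -2 * sp))
})

test_that("assembly builds the GIL block mask and per-layer heads", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(use_regulatory = TRUE, seed = 1),
                         modalities = c("continuous", "binary"))
  gil <- model$masks$gene_input
  expect_identical(sum(gil != 0), 2L * length(model$genes))
  # block structure: channel gene|modality connects only to node gene
  nz <- which(gil != 0, arr.ind = TRUE)
  expect_true(all(sub("\\|.*", "", rownames(gil)[nz[, 1]]) ==
                    colnames(gil)[nz[, 2]]))
  # heads: gene + regulatory + one per pathway layer
  expect_identical(model$stage_names,
                   c("gene", "regulatory", "pathway_1", "pathway_2"))
  no_reg <- model_config(use_regulatory = FALSE, seed = 1)
  m2 <- assemble_pnet(mask_stack(w$masks$masks["pathway_1"]), no_reg,
                      modalities = "continuous")
  expect_identical(m2$stage_names, c("gene", "pathway_1"))
  expect_length(m2$par$heads, 2L)

  expect_error(
    assemble_pnet(mask_stack(w$masks$masks["pathway_1"]),
                  model_config(use_regulatory = TRUE)),
    "regulatory")
})

test_that("toy_world masks include regulatory by default", {
  w <- toy_world()
  expect_true("regulatory" %in% w$masks$layer_names)
  model <- assemble_pnet(w$masks, model_config(use_regulatory = TRUE, seed = 1),
                         modalities = c("continuous", "binary"))
  expect_identical(model$stage_names,
                   c("gene", "regulatory", "pathway_1", "pathway_2"))
})

test_that("combined logit is a convex combination of head logits", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(seed = 2),
                         modalities = c("continuous", "binary"))
  pred <- forward_predict(model, w$cohort$modalities)
  expect_true(all(pred$head_weights >= 0))
  expect_equal(sum(pred$head_weights), 1)
  expect_equal(pred$combined_logit,
               drop(pred$per_layer_logits %*% pred$head_weights))
  expect_equal(pred$combined_probability, plogis(pred$combined_logit))
  # single-head model: combined logit equals that head's logit
  s1 <- mask_stack(list(pathway_1 = binn:::new_mask(
    w$masks$masks$pathway_1)))
  m1 <- assemble_pnet(s1, model_config(seed = 1), modalities = "continuous")
  m1$par$w_heads <- c(5, -1) # arbitrary weighting cannot change a convex combo
  p1 <- forward_predict(m1, w$cohort$modalities["continuous"])
  # all heads identical logit c -> combined = c
  m1$par$heads$gene$a[] <- 0; m1$par$heads$pathway_1$a[] <- 0
  m1$par$heads$gene$c <- 0.7; m1$par$heads$pathway_1$c <- 0.7
  pc <- forward_predict(m1, w$cohort$modalities["continuous"])
  expect_equal(unname(pc$combined_logit), rep(0.7, nrow(w$cohort$modalities$continuous)))
})

test_that("hand-built linear network reproduces a by-hand forward pass", {
  # 2 genes -> 1 pathway, linear activation, unit weights, zero biases
  h <- parse_pathway_relations(write_lines_tmp("TOP\tP"))
  s <- build_layer_masks(h, gene_membership(list(P = c("gA", "gB"))), n_layers = 1)
  model <- assemble_pnet(s, model_config(activation = "linear", seed = 1),
                         modalities = "m")
  model$par$layers$gene_input$W[model$masks$gene_input != 0] <- 1
  model$par$layers$pathway_1$W[model$masks$pathway_1 != 0] <- 1
  model$par$heads$gene$a <- c(1, 1); model$par$heads$gene$c <- 0
  model$par$heads$pathway_1$a <- 1; model$par$heads$pathway_1$c <- 0
  model$par$w_heads <- c(0, 0)
  x <- matrix(c(1, -1), 1, 2, dimnames = list(NULL, c("gA|m", "gB|m")))
  pred <- forward_predict(model, x)
  # gene stage h = (1, -1); gene head = 0; pathway node = 0; combined = 0
  expect_equal(unname(pred$per_layer_logits), matrix(c(0, 0), 1, 2))
  expect_equal(unname(pred$combined_logit), 0)
  x2 <- matrix(c(2, 1), 1, 2, dimnames = list(NULL, c("gA|m", "gB|m")))
  pred2 <- forward_predict(model, x2)
  expect_equal(unname(pred2$per_layer_logits), matrix(c(3, 3), 1, 2))
  expect_equal(unname(pred2$combined_logit), 3)
})

test_that("all-zero regulon leaves predictions identical to the regulatory-free model", {
  w <- toy_world(n_tfs = 0)
  masks_noreg <- build_layer_masks(w$kg$hierarchy, w$kg$membership, n_layers = 2)
  empty_reg <- matrix(0, length(rownames(masks_noreg$masks$pathway_1)),
                      length(rownames(masks_noreg$masks$pathway_1)))
  dimnames(empty_reg) <- list(rownames(masks_noreg$masks$pathway_1),
                              rownames(masks_noreg$masks$pathway_1))
  masks_reg <- mask_stack(c(masks_noreg$masks,
                            list(regulatory = binn:::new_mask(empty_reg))))
  m_with <- assemble_pnet(masks_reg, model_config(use_regulatory = TRUE, seed = 9),
                          modalities = c("continuous", "binary"))
  m_wo <- assemble_pnet(masks_noreg, model_config(seed = 9),
                        modalities = c("continuous", "binary"))
  # align shared parameters; the regulatory stage contributes exactly zero
  for (nm in names(m_wo$par$layers)) m_with$par$layers[[nm]] <- m_wo$par$layers[[nm]]
  for (nm in names(m_wo$par$heads)) m_with$par$heads[[nm]] <- m_wo$par$heads[[nm]]
  m_with$par$heads$regulatory$a[] <- 0; m_with$par$heads$regulatory$c <- 0
  m_with$par$w_heads <- c(0, -1e9, 0, 0) # zero weight on the regulatory head
  m_wo$par$w_heads <- c(0, 0, 0)
  p1 <- forward_predict(m_with, w$cohort$modalities)
  p2 <- forward_predict(m_wo, w$cohort$modalities)
  expect_equal(p1$combined_logit, p2$combined_logit, tolerance = 1e-12)
})

test_that("dense-limit forward pass equals a plain fully connected network", {
  set.seed(5)
  genes <- c("g1", "g2", "g3")
  ones <- function(r, c, rn, cn) binn:::new_mask(
    matrix(1, r, c, dimnames = list(rn, cn)))
  s <- mask_stack(list(pathway_1 = ones(3, 2, genes, c("p1", "p2")),
                       pathway_2 = ones(2, 1, c("p1", "p2"), "q")))
  model <- assemble_pnet(s, model_config(activation = "tanh", seed = 3),
                         modalities = "m")
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0(genes, "|m")))
  pred <- forward_predict(model, X)
  # independent dense oracle in plain matrix code
  W0 <- model$par$layers$gene_input$W; b0 <- model$par$layers$gene_input$b
  W1 <- model$par$layers$pathway_1$W; b1 <- model$par$layers$pathway_1$b
  W2 <- model$par$layers$pathway_2$W; b2 <- model$par$layers$pathway_2$b
  h0 <- tanh(sweep(X %*% W0, 2, b0, `+`))
  h1 <- tanh(sweep(h0 %*% W1, 2, b1, `+`))
  h2 <- tanh(sweep(h1 %*% W2, 2, b2, `+`))
  heads <- model$par$heads
  logits <- cbind(h0 %*% heads$gene$a + heads$gene$c,
                  h1 %*% heads$pathway_1$a + heads$pathway_1$c,
                  h2 %*% heads$pathway_2$a + heads$pathway_2$c)
  expect_equal(unname(pred$per_layer_logits), unname(logits))
  expect_equal(pred$combined_logit, drop(logits %*% rep(1 / 3, 3)))
})

test_that("random sparse rewiring preserves per-layer connection counts", {
  w <- toy_world()
  counts <- count_connections(w$masks)
  for (seed in 1:10) {
    r <- make_random_sparse(w$masks, seed = seed)
    expect_identical(count_connections(r), counts)
  }
  # reproducible per seed; different seeds move positions
  r1 <- make_random_sparse(w$masks, seed = 4)
  r2 <- make_random_sparse(w$masks, seed = 4)
  expect_identical(r1$masks, r2$masks)
  r3 <- make_random_sparse(w$masks, seed = 5)
  expect_false(identical(r1$masks$pathway_1, r3$masks$pathway_1))
  # full mask has no freedom
  full <- mask_stack(list(pathway_1 = binn:::new_mask(
    matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("u", "v"))))))
  expect_identical(make_random_sparse(full, 1)$masks$pathway_1,
                   full$masks$pathway_1)
})

test_that("gene-set first layer encodes membership and matches reference counts", {
  w <- toy_world()
  sets <- gene_membership(list(S1 = c("g001", "g002"), S2 = c("g002", "g003"),
                               S3 = c("g004", "g005", "g006")),
                          genes = w$kg$membership$genes)
  gs <- make_geneset_first_layer(sets, w$masks, seed = 1)
  first <- gs$masks$pathway_1
  nz <- which(first != 0, arr.ind = TRUE)
  got <- paste(rownames(first)[nz[, 1]], colnames(first)[nz[, 2]])
  expect_setequal(got, c("g001 S1", "g002 S1", "g002 S2", "g003 S2",
                         "g004 S3", "g005 S3", "g006 S3"))
  # subsequent layer counts equal the reference stack's
  ref_counts <- count_connections(w$masks)
  gs_counts <- count_connections(gs)
  expect_identical(gs_counts[["pathway_2"]], ref_counts[["pathway_2"]])
  # every gene in every set -> all-ones first mask
  allsets <- gene_membership(list(S = w$kg$membership$genes),
                             genes = w$kg$membership$genes)
  ga <- make_geneset_first_layer(allsets, w$masks, seed = 1)
  expect_true(all(ga$masks$pathway_1 == 1))
})

test_that("backprop gradients match central finite differences", {
  w <- toy_world()
  model <- assemble_pnet(w$masks, model_config(use_regulatory = TRUE,
                                               dropout_rate = 0, seed = 3),
                         modalities = c("continuous", "binary"))
  X <- binn:::align_input(model, w$cohort$modalities)[1:6, ]
  y <- w$cohort$labels[1:6]
  lg <- binn:::pnet_loss_grads(model, X, y, rep(1, 6), weight_decay = 0.01)
  eps <- 1e-6
  numgrad <- function(setter, getter, idx) {
    m1 <- setter(model, getter(model) + eps * (seq_along(getter(model)) %in% idx))
    m2 <- setter(model, getter(model) - eps * (seq_along(getter(model)) %in% idx))
    (binn:::pnet_loss_grads(m1, X, y, rep(1, 6), weight_decay = 0.01)$loss -
       binn:::pnet_loss_grads(m2, X, y, rep(1, 6), weight_decay = 0.01)$loss) /
      (2 * eps)
  }
  checks <- list(
    list(g = function() lg$grads$layers$pathway_1$W,
         get = function(m) m$par$layers$pathway_1$W,
         set = function(m, v) { m$par$layers$pathway_1$W <- matrix(v, nrow(m$par$layers$pathway_1$W)); m },
         idx = which(w$masks$masks$pathway_1 != 0)[2]),
    list(g = function() lg$grads$layers$regulatory$W,
         get = function(m) m$par$layers$regulatory$W,
         set = function(m, v) { m$par$layers$regulatory$W <- matrix(v, nrow(m$par$layers$regulatory$W)); m },
         idx = which(w$masks$masks$regulatory != 0)[1]),
    list(g = function() lg$grads$heads$pathway_1$a,
         get = function(m) m$par$heads$pathway_1$a,
         set = function(m, v) { m$par$heads$pathway_1$a <- v; m },
         idx = 2L),
    list(g = function() lg$grads$w_heads,
         get = function(m) m$par$w_heads,
         set = function(m, v) { m$par$w_heads <- v; m },
         idx = 3L)
  )
  for (ck in checks) {
    expect_equal(unname(ck$g()[ck$idx]), numgrad(ck$set, ck$get, ck$idx),
                 tolerance = 1e-5)
  }
})
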