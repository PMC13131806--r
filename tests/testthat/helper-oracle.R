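# Brute-force enumeration of knowledge-licensed mask entries, written as a
# direct double loop over raw edges and memberships — independent of the
# package's mask builder.
licensed_pairs <- function(h, m, n_layers) {
  lay <- h$layer
  usable <- lapply(m$member_of, function(p) p[lay[p] <= n_layers])
  attach <- vapply(usable, function(p) if (length(p)) min(lay[p]) else NA_integer_,
                   integer(1))
  genes <- names(attach)[!is.na(attach)]
  out <- character(0)
  lic <- function(mask, r, c) sprintf("%s|%s|%s", mask, r, c)
  rep_at <- function(id, own_layer, k) {
    if (k == own_layer) id else sprintf("%s.copy%d", id, k)
  }
  for (g in genes) {
    lg <- attach[[g]]
    if (lg == 1) {
      for (p in usable[[g]][lay[usable[[g]]] == 1]) {
        out <- c(out, lic("pathway_1", g, p))
      }
    } else {
      out <- c(out, lic("pathway_1", g, sprintf("%s.copy1", g)))
      if (lg > 2) for (k in 2:(lg - 1)) {
        out <- c(out, lic(paste0("pathway_", k), sprintf("%s.copy%d", g, k - 1),
                          sprintf("%s.copy%d", g, k)))
      }
      for (p in usable[[g]][lay[usable[[g]]] == lg]) {
        out <- c(out, lic(paste0("pathway_", lg), sprintf("%s.copy%d", g, lg - 1), p))
      }
    }
  }
  for (i in seq_len(nrow(h$edges))) {
    P <- h$edges$parent[i]; ch <- h$edges$child[i]
    if (lay[[P]] == lay[[ch]] + 1 && lay[[P]] <= n_layers) {
      out <- c(out, lic(paste0("pathway_", lay[[P]]), ch, P))
    } else if (lay[[P]] > lay[[ch]] + 1) {
      hi <- min(lay[[P]] - 1, n_layers)
      if (hi > lay[[ch]]) for (k in (lay[[ch]] + 1):hi) {
        out <- c(out, lic(paste0("pathway_", k), rep_at(ch, lay[[ch]], k - 1),
                          sprintf("%s.copy%d", ch, k)))
      }
      if (lay[[P]] <= n_layers) {
        out <- c(out, lic(paste0("pathway_", lay[[P]]),
                          sprintf("%s.copy%d", ch, lay[[P]] - 1), P))
      }
    }
  }
  unique(out)
}

# Compare every mask's nonzeros against the licensed enumeration.
expect_masks_licensed <- function(s, h, m, n_layers) {
  lic <- licensed_pairs(h, m, n_layers)
  for (nm in setdiff(s$layer_names, "regulatory")) {
    mk <- s$masks[[nm]]
    nz <- which(mk != 0, arr.ind = TRUE)
    got <- sprintf("%s|%s|%s", nm, rownames(mk)[nz[, 1]], colnames(mk)[nz[, 2]])
    expect_setequal(got, lic[startsWith(lic, paste0(nm, "|"))])
  }
}
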