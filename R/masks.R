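# Connectivity masks ------------------------------------------------------
#
# A mask is a dense numeric matrix with entries in {-1, 0, +1}, dimnames
# giving the row/column node identifiers, and two attributes:
#   frozen      logical matrix marking copy-through connections whose
#               effective weight is fixed at exactly 1 (never trained)
#   passthrough logical vector over columns marking copy nodes, which carry
#               their single input forward linearly (no activation, no bias)
# A mask stack is the ordered list of masks defining one model variant.

new_mask <- function(mat, frozen = NULL, passthrough = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  storage.mode(mat) <- "double"
  if (is.null(frozen)) frozen <- array(FALSE, dim = dim(mat))
  dimnames(frozen) <- dimnames(mat)
  if (is.null(passthrough)) {
    passthrough <- stats::setNames(rep(FALSE, ncol(mat)), colnames(mat))
  }
  attr(mat, "frozen") <- frozen
  attr(mat, "passthrough") <- passthrough
  mat
}

mask_frozen <- function(m) attr(m, "frozen") %||% array(FALSE, dim = dim(m))
mask_passthrough <- function(m) {
  attr(m, "passthrough") %||% stats::setNames(rep(FALSE, ncol(m)), colnames(m))
}

copy_node_name <- function(id, k) sprintf("%s.copy%d", id, k)
copy_node_origin <- function(id) sub("\\.copy[0-9]+$", "", id)
is_copy_node <- function(id) grepl("\\.copy[0-9]+$", id)

#' Mask stack
#'
#' Validates and wraps an ordered named list of connectivity masks. Pathway
#' masks must chain: the column identifiers of mask k are the row identifiers
#' of mask k+1. The square gene-by-gene `regulatory` mask is exempt from
#' chaining.
#'
#' @param masks named list of mask matrices (see [build_layer_masks()]).
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(masks) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  chain <- masks[setdiff(names(masks), "regulatory")]
  if (length(chain) > 1) {
    for (i in seq_len(length(chain) - 1L)) {
      if (!identical(colnames(chain[[i]]), rownames(chain[[i + 1L]]))) {
        stop("mask chaining violated between ", names(chain)[i], " and ",
             names(chain)[i + 1L])
      }
    }
  }
  for (nm in names(masks)) {
    v <- masks[[nm]]
    if (!all(v %in% c(-1, 0, 1))) stop("mask ", nm, " has entries outside {-1,0,+1}")
  }
  structure(list(masks = masks, layer_names = names(masks)), class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat("Mask stack with", length(x$masks), "masks:\n")
  for (nm in x$layer_names) {
    m <- x$masks[[nm]]
    cat(sprintf("  %-12s %5d x %-5d  %d connections\n", nm, nrow(m), ncol(m),
                sum(m != 0)))
  }
  invisible(x)
}

#' Build layer-wise sparsity masks from a knowledge graph
#'
#' Translates a pathway hierarchy, gene-to-pathway membership, and optional
#' signed regulon into the ordered masks of a pathway-guided network with
#' `n_layers` pathway layers:
#'
#' * `pathway_1`: genes x layer-1 nodes. A gene connects to its most specific
#'   (lowest-layer) pathway memberships only. A gene whose most specific
#'   membership lies at layer l > 1 enters a frozen copy-through chain
#'   (`gene.copy1`, `gene.copy2`, ...) that carries its value up to layer l,
#'   where trainable connections to its pathways are made.
#' * `pathway_k` (k = 2..n_layers): layer k-1 nodes x layer k nodes. Entry
#'   (c, p) = 1 for every hierarchy edge (p, c) with layer(p) = layer(c) + 1.
#'   Edges that skip layers are re-anchored through frozen copy-through
#'   nodes; chains are capped at `n_layers` when the skip parent itself lies
#'   above the retained layers, so the child's signal still reaches the top
#'   retained layer.
#' * `regulatory` (when `regulon` is given): square gene x gene mask with
#'   entry (g, t) = sign for every signed edge (t, g, sign) — column t
#'   collects t's targets — plus a +1 self-link (t, t) for every TF. Non-TF
#'   columns have no incoming connections.
#'
#' Identifiers are ordered lexicographically within each layer so masks do
#' not depend on input file row order.
#'
#' @param hierarchy a [pathway_hierarchy()].
#' @param membership a [gene_membership()]; every referenced pathway must
#'   exist in the hierarchy.
#' @param regulon optional [regulatory_network()].
#' @param n_layers number of pathway layers to retain (1 <= n_layers <= depth).
#' @param unmapped what to do with genes having no usable pathway membership:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return A [mask_stack()] with masks `pathway_1`, ..., `pathway_n_layers`
#'   and, when a regulon is supplied, `regulatory`.
#' @export
build_layer_masks <- function(hierarchy, membership, regulon = NULL, n_layers,
                              unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(hierarchy, "pathway_hierarchy"),
            inherits(membership, "gene_membership"))
  lay <- hierarchy$layer
  n_layers <- as.integer(n_layers)
  if (length(lay) == 0) stop("empty hierarchy")
  if (n_layers < 1 || n_layers > max(lay)) {
    stop("n_layers must be between 1 and the hierarchy depth (", max(lay), ")")
  }
  referenced <- unique(unlist(membership$member_of, use.names = FALSE))
  unknown <- setdiff(referenced, hierarchy$nodes)
  if (length(unknown) > 0) {
    stop("membership references pathways absent from the hierarchy: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(membership$genes) == 0) stop("gene list is empty")

  # gene attachment: most specific membership among retained layers
  attach_layer <- integer(0)
  attach_pws <- list()
  dropped <- character(0)
  for (g in membership$genes) {
    mems <- membership$member_of[[g]]
    mems <- mems[lay[mems] <= n_layers]
    if (length(mems) == 0) {
      dropped <- c(dropped, g)
    } else {
      lg <- min(lay[mems])
      attach_layer[[g]] <- lg
      attach_pws[[g]] <- sort(mems[lay[mems] == lg])
    }
  }
  if (length(dropped) > 0) {
    if (unmapped == "error") {
      stop(length(dropped), " gene(s) have no pathway membership within the ",
           "retained layers: ", paste(utils::head(dropped, 5), collapse = ", "))
    }
    warning(length(dropped), " gene(s) without usable pathway membership ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "))
  }
  genes <- sort(names(attach_layer))
  if (length(genes) == 0) stop("no genes could be attached to the hierarchy")

  # copy-through needs: pathway c needs copies at layers (layer(c)+1)..need_p[c]
  need_p <- stats::setNames(integer(0), character(0))
  ed <- hierarchy$edges
  for (i in seq_len(nrow(ed))) {
    P <- ed$parent[i]; ch <- ed$child[i]
    if (lay[[P]] > lay[[ch]] + 1L) {
      hi <- min(lay[[P]] - 1L, n_layers)
      if (hi > lay[[ch]]) {
        cur <- if (ch %in% names(need_p)) need_p[[ch]] else 0L
        need_p[[ch]] <- max(cur, hi)
      }
    }
  }
  # gene copies at layers 1..(attach_layer-1)
  need_g <- attach_layer[genes] - 1L

  layer_nodes <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    real <- hierarchy$nodes[lay[hierarchy$nodes] == k]
    pcp <- names(need_p)[need_p >= k & lay[names(need_p)] < k]
    gcp <- genes[need_g >= k]
    layer_nodes[[k]] <- sort(c(real,
                               copy_node_name(pcp, k)[seq_along(pcp)],
                               copy_node_name(gcp, k)[seq_along(gcp)]))
  }

  masks <- list()
  # pathway_1: genes -> layer-1 nodes
  tri <- list(r = character(0), c = character(0), frozen = logical(0))
  add <- function(tri, r, c, frozen) {
    tri$r <- c(tri$r, r); tri$c <- c(tri$c, c)
    tri$frozen <- c(tri$frozen, rep(frozen, length(r)))
    tri
  }
  for (g in genes) {
    if (attach_layer[[g]] == 1L) {
      tri <- add(tri, rep(g, length(attach_pws[[g]])), attach_pws[[g]], FALSE)
    } else {
      tri <- add(tri, g, copy_node_name(g, 1L), TRUE)
    }
  }
  masks$pathway_1 <- triplets_to_mask(tri, genes, layer_nodes[[1L]])

  if (n_layers > 1L) {
    for (k in 2:n_layers) {
      tri <- list(r = character(0), c = character(0), frozen = logical(0))
      for (i in seq_len(nrow(ed))) {
        P <- ed$parent[i]; ch <- ed$child[i]
        if (lay[[P]] != k) next
        row <- if (lay[[ch]] == k - 1L) ch else copy_node_name(ch, k - 1L)
        tri <- add(tri, row, P, FALSE)
      }
      # pathway copy-chain steps into layer k
      for (o in names(need_p)) {
        if (need_p[[o]] >= k && lay[[o]] < k) {
          row <- if (lay[[o]] == k - 1L) o else copy_node_name(o, k - 1L)
          tri <- add(tri, row, copy_node_name(o, k), TRUE)
        }
      }
      # gene attachment at layer k and gene copy-chain steps
      for (g in genes) {
        if (attach_layer[[g]] == k) {
          tri <- add(tri, rep(copy_node_name(g, k - 1L), length(attach_pws[[g]])),
                     attach_pws[[g]], FALSE)
        }
        if (need_g[[g]] >= k) {
          tri <- add(tri, copy_node_name(g, k - 1L), copy_node_name(g, k), TRUE)
        }
      }
      masks[[paste0("pathway_", k)]] <-
        triplets_to_mask(tri, layer_nodes[[k - 1L]], layer_nodes[[k]])
    }
  }

  if (!is.null(regulon)) {
    stopifnot(inherits(regulon, "regulatory_network"))
    mat <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
    re <- regulon$edges
    keep <- re$tf %in% genes & re$target %in% genes
    re <- re[keep, , drop = FALSE]
    for (i in seq_len(nrow(re))) {
      if (re$tf[i] == re$target[i] && re$sign[i] < 0) {
        stop("regulon self-edge (", re$tf[i], ", ", re$tf[i],
             ") conflicts with the +1 TF self-link")
      }
      mat[re$target[i], re$tf[i]] <- re$sign[i]
    }
    for (t in intersect(regulon$tfs, genes)) mat[t, t] <- 1
    masks$regulatory <- new_mask(mat)
  }

  mask_stack(masks)
}

triplets_to_mask <- function(tri, rows, cols) {
  mat <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  frz <- array(FALSE, dim = dim(mat), dimnames = dimnames(mat))
  if (length(tri$r) > 0) {
    ij <- cbind(match(tri$r, rows), match(tri$c, cols))
    if (anyNA(ij)) stop("internal error: triplet references unknown node")
    mat[ij] <- 1
    frz[ij[tri$frozen, , drop = FALSE]] <- TRUE
  }
  new_mask(mat, frozen = frz,
           passthrough = stats::setNames(is_copy_node(cols), cols))
}

#' Per-layer connection counts
#'
#' @param s a [mask_stack()].
#' @return Named integer vector of nonzero entries per mask.
#' @export
count_connections <- function(s) {
  stopifnot(inherits(s, "mask_stack"))
  vapply(s$masks, function(m) sum(m != 0), integer(1))
}

#' Degree-matched random sparse baseline
#'
#' For each mask, draws a mask of identical shape with exactly the same
#' number of nonzero entries at positions chosen uniformly without
#' replacement (the multiset of nonzero values is permuted onto the new
#' positions). Copy-through annotations are not carried over: the random
#' baseline has no frozen connections or pass-through nodes.
#'
#' @param s a [mask_stack()].
#' @param seed integer seed; the same seed reproduces the same masks.
#' @return A [mask_stack()] with per-layer connection counts equal to
#'   `count_connections(s)`.
#' @export
make_random_sparse <- function(s, seed) {
  stopifnot(inherits(s, "mask_stack"))
  set.seed(as.integer(seed))
  masks <- lapply(s$masks, function(m) {
    vals <- m[m != 0]
    k <- length(vals)
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    if (k > 0) {
      pos <- sample.int(length(m), k)
      out[pos] <- if (k > 1) sample(vals) else vals
    }
    new_mask(out)
  })
  mask_stack(masks)
}

#' Gene-set first layer (Hallmark-style baseline)
#'
#' Builds a stack whose first hidden layer bundles genes into known gene
#' sets (first mask = gene-to-set membership) while subsequent layers are
#' random sparse layers whose shapes and connection counts match a reference
#' pathway-guided stack.
#'
#' @param sets a [gene_membership()] (e.g. parsed from a Hallmark GMT).
#' @param reference a [mask_stack()] supplying the shapes and per-layer
#'   connection counts of the subsequent layers.
#' @param seed integer seed for the random subsequent layers.
#' @return A [mask_stack()].
#' @export
make_geneset_first_layer <- function(sets, reference, seed) {
  stopifnot(inherits(sets, "gene_membership"), inherits(reference, "mask_stack"))
  genes <- rownames(reference$masks[[1]])
  set_ids <- sort(names(sets$sets))
  if (length(set_ids) == 0) stop("gene sets are empty")
  first <- matrix(0, length(genes), length(set_ids),
                  dimnames = list(genes, set_ids))
  for (sid in set_ids) {
    hit <- intersect(sets$sets[[sid]], genes)
    first[hit, sid] <- 1
  }
  masks <- list(pathway_1 = new_mask(first))
  ref_names <- setdiff(reference$layer_names, "regulatory")
  set.seed(as.integer(seed))
  prev_cols <- set_ids
  if (length(ref_names) > 1) {
    for (k in 2:length(ref_names)) {
      ref <- reference$masks[[ref_names[k]]]
      out_ids <- colnames(ref)
      target_nnz <- min(sum(ref != 0), length(prev_cols) * length(out_ids))
      m <- matrix(0, length(prev_cols), length(out_ids),
                  dimnames = list(prev_cols, out_ids))
      if (target_nnz > 0) m[sample.int(length(m), target_nnz)] <- 1
      masks[[ref_names[k]]] <- new_mask(m)
      prev_cols <- out_ids
    }
  }
  mask_stack(masks)
}

# Serialization ------------------------------------------------------------

#' Write a mask stack to a directory
#'
#' Each mask becomes a sparse triplet CSV (`row_id,col_id,value,frozen`,
#' sorted by column then row) plus a JSON sidecar recording layer names, the
#' full row/column identifier orders and the pass-through flags, so that
#' [read_mask_stack()] reproduces the stack bit-exactly.
#'
#' @param s a [mask_stack()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mask_stack <- function(s, dir) {
  stopifnot(inherits(s, "mask_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- list(layer_names = as.list(s$layer_names), masks = list())
  for (i in seq_along(s$masks)) {
    nm <- s$layer_names[i]
    m <- s$masks[[nm]]
    nz <- which(m != 0, arr.ind = TRUE)
    df <- data.frame(
      row_id = rownames(m)[nz[, 1]],
      col_id = colnames(m)[nz[, 2]],
      value = as.integer(m[nz]),
      frozen = mask_frozen(m)[nz],
      stringsAsFactors = FALSE
    )
    df <- df[order(df$col_id, df$row_id), , drop = FALSE]
    file <- sprintf("mask_%02d_%s.csv", i, nm)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    index$masks[[nm]] <- list(
      file = file,
      row_index = as.list(rownames(m)),
      col_index = as.list(colnames(m)),
      passthrough = as.list(unname(mask_passthrough(m)))
    )
  }
  jsonlite::write_json(index, file.path(dir, "mask_stack.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a mask stack written by [write_mask_stack()]
#'
#' @param dir directory containing `mask_stack.json` and the triplet CSVs.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "mask_stack.json"))
  masks <- list()
  for (nm in unlist(index$layer_names)) {
    info <- index$masks[[nm]]
    rows <- unlist(info$row_index)
    cols <- unlist(info$col_index)
    df <- utils::read.csv(file.path(dir, info$file), stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "logical"))
    mat <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    frz <- array(FALSE, dim = dim(mat), dimnames = dimnames(mat))
    if (nrow(df) > 0) {
      ij <- cbind(match(df$row_id, rows), match(df$col_id, cols))
      mat[ij] <- df$value
      frz[ij[df$frozen, , drop = FALSE]] <- TRUE
    }
    pt <- stats::setNames(as.logical(unlist(info$passthrough)), cols)
    masks[[nm]] <- new_mask(mat, frozen = frz, passthrough = pt)
  }
  mask_stack(masks)
}
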