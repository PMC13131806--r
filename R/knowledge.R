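#' Pathway hierarchy
#'
#' A rooted directed acyclic graph of pathway identifiers with a per-node
#' layer assignment. Layer 1 holds the most specific (deepest) pathways: a
#' node's layer is the length of the longest directed path from it down to a
#' leaf, plus one, so every leaf sits at layer 1 and a parent is always at
#' least one layer above each of its children.
#'
#' @param nodes character vector of pathway identifiers.
#' @param edges data frame with columns `parent`, `child`.
#' @return An object of class `pathway_hierarchy`: a list with elements
#'   `nodes`, `edges`, `roots` (nodes with no parent) and `layer` (named
#'   integer vector).
#' @export
pathway_hierarchy <- function(nodes, edges) {
  nodes <- as.character(nodes)
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  unknown <- setdiff(c(edges$parent, edges$child), nodes)
  if (length(unknown) > 0) {
    stop("edges reference unknown nodes: ", paste(unknown, collapse = ", "))
  }
  layer <- assign_layers(nodes, edges)
  roots <- setdiff(nodes, edges$child)
  structure(
    list(nodes = nodes, edges = edges, roots = roots, layer = layer),
    class = "pathway_hierarchy"
  )
}

# Longest path to a leaf (+1) per node; errors with one explicit cycle if the
# graph is not acyclic. Iterative DFS with colouring so deep hierarchies do
# not overflow the call stack.
assign_layers <- function(nodes, edges) {
  if (length(nodes) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  kids <- split(edges$child, factor(edges$parent, levels = nodes))
  layer <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] == 2L) next
    stack <- list(start)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      if (state[[v]] == 0L) {
        state[[v]] <- 1L
        for (ch in kids[[v]]) {
          if (state[[ch]] == 1L) {
            path <- vapply(stack, identity, character(1))
            cyc <- c(path[seq(match(ch, path), length(path))], ch)
            stop("cycle detected in pathway relations: ",
                 paste(cyc, collapse = " -> "))
          }
          if (state[[ch]] == 0L) stack[[length(stack) + 1L]] <- ch
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (state[[v]] == 1L) {
          state[[v]] <- 2L
          ch <- kids[[v]]
          layer[[v]] <- if (length(ch) == 0) 1L else 1L + max(layer[ch])
        }
      }
    }
  }
  layer
}

#' Parse a pathway parent-child relation table
#'
#' Reads a two-column tab-separated file of `parent<TAB>child` pathway
#' identifier pairs (the dialect used by hierarchical pathway databases such
#' as Reactome; no header) and returns the hierarchy with layers assigned.
#'
#' @param path path to the relations file.
#' @return A [pathway_hierarchy()].
#' @export
parse_pathway_relations <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop("malformed relation line ", idx[bad[1]],
         ": expected exactly 2 tab-separated fields")
  }
  parent <- vapply(parts, `[[`, character(1), 1L)
  child <- vapply(parts, `[[`, character(1), 2L)
  nodes <- unique(c(parent, child))
  pathway_hierarchy(nodes, data.frame(parent = parent, child = child,
                                      stringsAsFactors = FALSE))
}

#' Gene-to-pathway membership
#'
#' @param sets named list mapping a set/pathway identifier to a character
#'   vector of member genes.
#' @param genes optional gene ordering; defaults to first-appearance order
#'   across sets.
#' @return An object of class `gene_membership` with elements `genes`
#'   (ordered, duplicate-free), `sets` (named list, members deduplicated) and
#'   `member_of` (named list gene -> character vector of set ids).
#' @export
gene_membership <- function(sets, genes = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(genes)) genes <- unique(unlist(sets, use.names = FALSE))
  genes <- as.character(genes %||% character(0))
  stopifnot(!anyDuplicated(genes))
  member_of <- stats::setNames(vector("list", length(genes)), genes)
  for (s in names(sets)) {
    for (g in sets[[s]]) {
      member_of[[g]] <- c(member_of[[g]], s)
    }
  }
  structure(
    list(genes = genes, sets = sets, member_of = member_of),
    class = "gene_membership"
  )
}

#' Parse a GMT gene-set file
#'
#' GMT lines are `set_name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' returned in first-appearance order; duplicate genes within one set are
#' deduplicated.
#'
#' @param path path to the GMT file.
#' @param dialect gene-set file dialect; only `"gmt"` is supported.
#' @return A [gene_membership()].
#' @export
parse_gene_sets <- function(path, dialect = "gmt") {
  stopifnot(file.exists(path))
  dialect <- match.arg(dialect, "gmt")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    stop("malformed GMT line ", idx[bad[1]], ": expected >= 3 tab-separated fields")
  }
  sets <- stats::setNames(
    lapply(parts, function(p) unique(p[-c(1L, 2L)])),
    vapply(parts, `[[`, character(1), 1L)
  )
  gene_membership(sets)
}

#' Signed transcription-factor regulon
#'
#' @param edges data frame with columns `tf`, `target`, `sign`
#'   (sign in -1/+1).
#' @return An object of class `regulatory_network` with elements `tfs` (set
#'   of source gene symbols) and `edges`.
#' @export
regulatory_network <- function(edges = data.frame(tf = character(0),
                                                  target = character(0),
                                                  sign = integer(0))) {
  stopifnot(is.data.frame(edges), all(c("tf", "target", "sign") %in% names(edges)))
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop("regulatory edge signs must be -1 or +1")
  }
  key <- paste(edges$tf, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    # same-sign duplicates collapse; conflicting signs are an input error
    agg <- tapply(edges$sign, key, function(s) length(unique(s)))
    conflict <- names(agg)[agg > 1]
    if (length(conflict) > 0) {
      pair <- strsplit(conflict[1], "\r", fixed = TRUE)[[1]]
      stop("conflicting signs for regulatory pair (", pair[1], ", ", pair[2], ")")
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(tfs = unique(edges$tf), edges = edges),
    class = "regulatory_network"
  )
}

#' Parse a signed TF-target edge list
#'
#' Reads a tab-separated regulon file with a header naming columns `source`,
#' `target` and `weight` (or `sign`), the dialect used by signed regulon
#' collections such as CollecTRI. Weights are collapsed to their sign; a zero
#' weight is rejected.
#'
#' @param path path to the regulon TSV.
#' @return A [regulatory_network()].
#' @export
parse_regulatory_edges <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (nrow(df) == 0 && ncol(df) <= 1) {
    return(regulatory_network())
  }
  wcol <- intersect(c("weight", "sign"), names(df))
  if (!all(c("source", "target") %in% names(df)) || length(wcol) == 0) {
    stop("regulon file must have columns source, target and weight (or sign)")
  }
  w <- as.numeric(df[[wcol[1]]])
  if (anyNA(w)) stop("non-numeric values in regulon ", wcol[1], " column")
  if (any(w == 0)) {
    stop("zero-valued sign at regulon row ", which(w == 0)[1])
  }
  regulatory_network(data.frame(
    tf = df$source, target = df$target, sign = as.integer(sign(w)),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat("Pathway hierarchy:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$roots), "root(s),",
      if (length(x$layer)) max(x$layer) else 0, "layer(s)\n")
  invisible(x)
}

#' @export
print.gene_membership <- function(x, ...) {
  cat("Gene membership:", length(x$genes), "genes in", length(x$sets), "sets\n")
  invisible(x)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", length(x$tfs), "TFs,", nrow(x$edges),
      "signed edges\n")
  invisible(x)
}
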