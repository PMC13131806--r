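# Importance stability across repeated runs --------------------------------

# Top-N node ids of one run; ties broken by score descending then node_id
# ascending, for determinism.
top_n_nodes <- function(tab, n, layer = NULL) {
  stopifnot(is.data.frame(tab))
  if (!is.null(layer)) tab <- tab[tab$layer %in% layer, , drop = FALSE]
  if (nrow(tab) < n) stop("run has fewer than N = ", n, " nodes")
  ord <- order(-tab$score, tab$node_id)
  tab$node_id[ord[seq_len(n)]]
}

#' Top-N Jaccard stability of importance rankings
#'
#' For each run, takes the N highest-scoring node identifiers, then returns
#' the mean Jaccard index |A ∩ B| / |A ∪ B| over all unordered pairs of
#' runs. 1 means the top-N sets are identical in every run.
#'
#' @param runs list (>= 2) of importance tables (data frames with `node_id`,
#'   `score`, optionally `layer`).
#' @param n_top N, the size of the top set (default 20).
#' @param layer optionally restrict to one layer label (e.g. `"gene"`)
#'   before ranking.
#' @return Mean pairwise Jaccard index in \[0, 1\].
#' @export
topn_jaccard_stability <- function(runs, n_top = 20L, layer = NULL) {
  stopifnot(is.list(runs), length(runs) >= 2)
  tops <- lapply(runs, top_n_nodes, n = n_top, layer = layer)
  pairs <- utils::combn(length(tops), 2)
  mean(apply(pairs, 2, function(p) {
    a <- tops[[p[1]]]; b <- tops[[p[2]]]
    length(intersect(a, b)) / length(union(a, b))
  }))
}

#' Per-node signal-to-noise ratio of importance across runs
#'
#' For every node shared across runs, computes the mean (`mu`) and sample
#' standard deviation (`sigma`, denominator n-1) of its importance score
#' over runs, and their ratio `snr = mu / sigma`. Nodes with `sigma = 0`
#' get `snr = NA` and are excluded from layerwise statistics (a message
#' reports how many).
#'
#' @param runs list (>= 2) of importance tables sharing a node index.
#' @return Data frame with columns `node_id`, `layer`, `mu`, `sigma`, `snr`.
#' @export
snr <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 2)
  all_tabs <- do.call(rbind, lapply(runs, function(t) {
    t[, c("node_id", "layer", "score")]
  }))
  key <- paste(all_tabs$node_id, all_tabs$layer, sep = "\r")
  counts <- table(key)
  if (any(counts < length(runs))) {
    missing <- names(counts)[counts < length(runs)][1]
    stop("node present in only some runs: ",
         strsplit(missing, "\r", fixed = TRUE)[[1]][1])
  }
  first <- all_tabs[!duplicated(key), c("node_id", "layer")]
  mu <- tapply(all_tabs$score, key, mean)
  sg <- tapply(all_tabs$score, key, stats::sd)
  k <- paste(first$node_id, first$layer, sep = "\r")
  out <- data.frame(
    node_id = first$node_id, layer = first$layer,
    mu = as.numeric(mu[k]), sigma = as.numeric(sg[k]),
    stringsAsFactors = FALSE
  )
  out$snr <- ifelse(out$sigma > 0, out$mu / out$sigma, NA_real_)
  nzero <- sum(out$sigma == 0)
  if (nzero > 0) {
    message(nzero, " node(s) with zero variance across runs; snr reported as NA")
  }
  rownames(out) <- NULL
  out
}

#' Layerwise Z-standardization of SNR values
#'
#' Within each layer, standardizes the defined SNR values to mean 0 and
#' sample standard deviation 1. Layers with fewer than two defined SNR
#' values, or zero SNR spread, are an error.
#'
#' @param snr_table data frame from [snr()].
#' @param on_degenerate what to do with a layer that has fewer than two
#'   defined SNR values or zero SNR spread: `"error"` (default) or `"skip"`
#'   (leave its `z` as NA with a message).
#' @return The table with an added `z` column (NA where snr is NA).
#' @export
layerwise_z <- function(snr_table, on_degenerate = c("error", "skip")) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(all(c("node_id", "layer", "snr") %in% names(snr_table)))
  snr_table$z <- NA_real_
  for (ln in unique(snr_table$layer)) {
    idx <- which(snr_table$layer == ln & is.finite(snr_table$snr))
    bad <- if (length(idx) < 2) {
      paste0("layer ", ln, " has fewer than 2 nodes with defined snr")
    } else if (stats::sd(snr_table$snr[idx]) == 0) {
      paste0("layer ", ln, " has zero snr spread; z undefined")
    }
    if (!is.null(bad)) {
      if (on_degenerate == "error") stop(bad)
      message(bad, "; layer skipped")
      next
    }
    v <- snr_table$snr[idx]
    snr_table$z[idx] <- (v - mean(v)) / stats::sd(v)
  }
  snr_table
}

#' Upper-tail p-value of a standard-normal Z score
#'
#' One-sided: `p = P(N(0,1) > z)`.
#'
#' @param z finite Z score(s).
#' @return p-value(s) in (0, 1).
#' @export
z_to_pvalue <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Stability report across repeated runs
#'
#' Combines the top-N Jaccard stability of the gene ranking with per-node
#' SNR, layerwise Z and upper-tail p-values.
#'
#' @param runs list (>= 2) of importance tables from [importance_table()].
#' @param n_top N for the Jaccard statistic (default 20, a sensitive choice
#'   for ranking stability of gene sets).
#' @param jaccard_layer layer label whose ranking the Jaccard statistic
#'   uses; default `"gene"`.
#' @return An object of class `stability_report`: list with `n_top`,
#'   `jaccard_mean` and `table` (node_id, layer, mu, sigma, snr, z, p).
#' @export
stability_report <- function(runs, n_top = 20L, jaccard_layer = "gene") {
  jac <- topn_jaccard_stability(runs, n_top = n_top, layer = jaccard_layer)
  tab <- layerwise_z(snr(runs), on_degenerate = "skip")
  tab$p <- ifelse(is.na(tab$z), NA_real_, z_to_pvalue(ifelse(is.na(tab$z), 0, tab$z)))
  structure(list(n_top = as.integer(n_top), jaccard_mean = jac, table = tab),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Importance stability: mean top-%d Jaccard = %.3f over %d nodes\n",
              x$n_top, x$jaccard_mean, nrow(x$table)))
  top <- x$table[order(-ifelse(is.na(x$table$z), -Inf, x$table$z)), ]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Write a stability report to CSV
#'
#' Columns `node_id,layer,mu,sigma,snr,z,p` followed by a summary line
#' recording `jaccard_mean`.
#'
#' @param report a [stability_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  cat(sprintf("# jaccard_mean,%0.10g,n_top,%d\n", report$jaccard_mean,
              report$n_top), file = path, append = TRUE)
  invisible(path)
}
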