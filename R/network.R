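# Homogeneous miRNA-miRNA network: nodes are responsive miRNAs, an edge
# records the enriched pathways (or consensus target genes) two miRNAs
# share. Edge weight = number shared; edge significance = hypergeometric
# upper-tail probability of sharing at least that many features when each
# miRNA's feature set is a random draw from a universe of N features.

#' Pair-overlap hypergeometric p-value
#'
#' Probability of observing at least `x` common features between one miRNA
#' annotated with `n` features and another annotated with `m`, both drawn
#' from a universe of `N` features:
#' P = 1 - sum_\{i=0\}^\{x-1\} C(m,i) C(N-m, n-i) / C(N,n).
#' Evaluated through the hypergeometric survival function (log-gamma based),
#' and symmetric in `n` and `m`.
#'
#' @param N universe size (e.g. 400 pathways, or 28000 genes).
#' @param n,m feature counts of the two miRNAs.
#' @param x number of shared features.
#' @return upper-tail p-value; 1 when `x = 0`.
#' @examples
#' pair_overlap_p(N = 400, n = 2, m = 3, x = 1) # 1194/79800
#' @export
pair_overlap_p <- function(N, n, m, x) {
  if (any(c(N, n, m, x) < 0) || any(c(N, n, m, x) != floor(c(N, n, m, x)))) {
    stop("pair_overlap_p: arguments must be non-negative integers")
  }
  if (n > N || m > N) stop("pair_overlap_p: feature counts exceed the universe")
  if (x > min(n, m)) stop("pair_overlap_p: shared count exceeds min(n, m)")
  stats::phyper(x - 1, m, N - m, n, lower.tail = FALSE)
}

#' Build the significance-filtered miRNA-miRNA network
#'
#' Every unordered pair of miRNAs sharing at least one feature is scored with
#' [pair_overlap_p()]; pairs with p below `alpha` become edges weighted by the
#' number of shared features. Nodes are the miRNAs incident to at least one
#' retained edge; miRNAs left without a partner are reported separately.
#' Pairs sharing nothing are never tested (their p is 1 by construction).
#'
#' @param annotations named list: miRNA id -> character vector of feature ids
#'   (enriched pathway ids in pathway mode, consensus target genes in gene
#'   mode); all sets must be non-empty.
#' @param N feature-universe size: the number of pathways in the collection
#'   (pathway mode) or genes in the reference universe (gene mode).
#' @param alpha retention threshold on the pair p-value (default 0.05).
#' @param direction optional named character vector ("up"/"down") attached to
#'   nodes.
#' @param mode label stored on the result ("pathway" or "gene").
#' @return object of class `"mirna_network"`: list with `edges` (data.frame
#'   `mirna_a`, `mirna_b`, `weight`, `p_value`, `shared_features`
#'   semicolon-joined), `nodes` (data.frame `mirna_id`, `direction`),
#'   `isolated` (character vector), `mode`, `N`, `alpha`, and
#'   `shared_sets` (list of shared-feature vectors per edge).
#' @export
build_network <- function(annotations, N, alpha = 0.05, direction = NULL,
                          mode = "pathway") {
  if (length(annotations) == 0L) stop("no annotated miRNAs supplied")
  if (any(lengths(annotations) == 0L)) {
    stop("empty feature sets must be omitted before network construction")
  }
  sizes <- lengths(lapply(annotations, unique))
  if (max(sizes) > N) {
    stop(sprintf("feature universe N = %d smaller than the largest feature set (%d); wrong mode/universe?",
                 N, max(sizes)))
  }
  ids <- sort(names(annotations))
  sets <- lapply(annotations[ids], unique)
  k <- length(ids)
  ea <- character(0); eb <- character(0); wt <- integer(0); pv <- numeric(0)
  shared <- list()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      si <- sets[[i]]
      for (j in seq.int(i + 1L, k)) {
        common <- intersect(si, sets[[j]])
        x <- length(common)
        if (x == 0L) next
        p <- pair_overlap_p(N, length(si), length(sets[[j]]), x)
        if (p < alpha) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
          wt <- c(wt, x); pv <- c(pv, p)
          shared[[length(shared) + 1L]] <- sort(common)
        }
      }
    }
  }
  node_ids <- sort(unique(c(ea, eb)))
  dir_col <- if (is.null(direction)) rep(NA_character_, length(node_ids)) else
    unname(direction[node_ids])
  structure(list(
    edges = data.frame(
      mirna_a = ea, mirna_b = eb, weight = wt, p_value = pv,
      shared_features = vapply(shared, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    ),
    shared_sets = shared,
    nodes = data.frame(mirna_id = node_ids, direction = dir_col,
                       stringsAsFactors = FALSE),
    isolated = setdiff(ids, node_ids),
    mode = mode, N = N, alpha = alpha
  ), class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("miRNA-miRNA network (%s mode, N = %d, alpha = %g)\n",
              x$mode, x$N, x$alpha))
  cat(sprintf("  %d interacting miRNAs, %d edges, %d isolated miRNAs\n",
              nrow(x$nodes), nrow(x$edges), length(x$isolated)))
  if (nrow(x$edges)) {
    cat(sprintf("  edge weights: %d-%d (median %g)\n",
                min(x$edges$weight), max(x$edges$weight),
                stats::median(x$edges$weight)))
  }
  invisible(x)
}

#' Most-targeted genes across network miRNAs
#'
#' Tallies, for each gene, how many distinct miRNAs carry it in their
#' consensus target set; genes hit by fewer than `min_mirnas` miRNAs are
#' dropped and the table is cut to the `top` rows (count descending, gene id
#' ascending within ties).
#'
#' @param consensus_sets named list restricted to the network's miRNAs.
#' @param min_mirnas minimum number of targeting miRNAs (default 2).
#' @param top number of rows to return (default 30).
#' @return data.frame with columns `gene_id`, `frequency`.
#' @export
most_targeted_genes <- function(consensus_sets, min_mirnas = 2, top = 30) {
  genes <- unlist(lapply(consensus_sets, unique), use.names = FALSE)
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(0), frequency = integer(0)))
  }
  tab <- table(genes)
  tab <- tab[tab >= min_mirnas]
  if (length(tab) == 0L) {
    return(data.frame(gene_id = character(0), frequency = integer(0)))
  }
  out <- data.frame(gene_id = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}
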