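# Degree-centrality ranking and dataset-level network summaries.

#' Degree centrality table
#'
#' Counts each node's distinct neighbours (unweighted degree, as reported by
#' Cytoscape's NetworkAnalyzer); the weighted degree (sum of incident edge
#' weights) is appended as an extra column. Sorted by degree descending,
#' miRNA id ascending within ties.
#'
#' @param net `"mirna_network"` object from [build_network()].
#' @return data.frame with columns `mirna_id`, `degree`, `weighted_degree`,
#'   `direction`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  ids <- net$nodes$mirna_id
  deg <- setNames(integer(length(ids)), ids)
  wdeg <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$mirna_a[i]; b <- net$edges$mirna_b[i]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    wdeg[a] <- wdeg[a] + net$edges$weight[i]
    wdeg[b] <- wdeg[b] + net$edges$weight[i]
  }
  out <- data.frame(mirna_id = ids, degree = unname(deg[ids]),
                    weighted_degree = unname(wdeg[ids]),
                    direction = net$nodes$direction,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dataset-level network summary
#'
#' Counts (i) interacting miRNAs — nodes with at least one retained edge —
#' and (ii) distinct features shared by at least two of the network's miRNAs
#' (the "shared pathways" / "shared target genes" tallies of pathway- and
#' gene-mode analyses).
#'
#' @param net `"mirna_network"` object.
#' @param annotations the annotation map the network was built from,
#'   restricted or not — only the network's nodes are counted.
#' @return data.frame with one row: `n_interacting_mirnas`,
#'   `n_shared_features`, `n_edges`.
#' @export
network_summary <- function(net, annotations) {
  stopifnot(inherits(net, "mirna_network"))
  ids <- net$nodes$mirna_id
  feats <- unlist(lapply(annotations[ids], unique), use.names = FALSE)
  shared <- if (length(feats)) sum(table(feats) >= 2L) else 0L
  data.frame(n_interacting_mirnas = length(ids),
             n_shared_features = as.integer(shared),
             n_edges = nrow(net$edges))
}
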