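# Markov clustering of the weighted miRNA-miRNA network. Flow simulation on
# the column-stochastic adjacency matrix: expansion (matrix power) spreads
# flow along longer walks, inflation (entry-wise power + renormalization)
# sharpens it, and the process converges to a doubly idempotent matrix whose
# attractor rows define the clusters.

#' Threshold network edges by weight
#'
#' Retains edges with weight at least `min_weight`; nodes left without any
#' incident edge are moved to the `isolated` slot and excluded from
#' clustering.
#'
#' @param net `"mirna_network"` object.
#' @param min_weight minimum edge weight to keep (default 2.9, so integer
#'   weights of 3 and above survive).
#' @return thresholded `"mirna_network"` object.
#' @export
threshold_edges <- function(net, min_weight = 2.9) {
  stopifnot(inherits(net, "mirna_network"))
  keep <- net$edges$weight >= min_weight
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$mirna_a, edges$mirna_b)))
  out <- net
  out$edges <- edges
  out$shared_sets <- net$shared_sets[keep]
  out$isolated <- sort(unique(c(net$isolated,
                                setdiff(net$nodes$mirna_id, node_ids))))
  out$nodes <- net$nodes[net$nodes$mirna_id %in% node_ids, , drop = FALSE]
  rownames(out$nodes) <- NULL
  out$min_weight <- min_weight
  out
}

adjacency_matrix <- function(net) {
  ids <- net$nodes$mirna_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$mirna_a[i]; b <- net$edges$mirna_b[i]
    A[a, b] <- A[b, a] <- net$edges$weight[i]
  }
  A
}

#' Markov clustering of a weighted network
#'
#' Builds the weighted adjacency matrix with self-loops (loop weight = the
#' node's maximum incident edge weight), column-normalizes it, and iterates
#' expansion (matrix power `expansion`) followed by inflation (entry-wise
#' power `inflation` and renormalization) with pruning of entries below
#' `prune`, until the largest entry change falls below `tol` or `max_iter`
#' is reached. Attractor rows (nonzero diagonal mass) define clusters; a node
#' attracted to several clusters is assigned to the one holding the most
#' steady-state mass, ties broken by lowest cluster id. Clusters are sorted
#' by size descending, then by smallest member id.
#'
#' @param net `"mirna_network"` object (typically after [threshold_edges()]).
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the max entry change (default 1e-6).
#' @param prune entries below this are zeroed after each inflation
#'   (default 1e-5).
#' @return object of class `"mcl_clustering"`: list with `clusters` (list of
#'   member id vectors), `membership` (named integer vector), `converged`,
#'   `iterations`, and `net` (the clustered network).
#' @export
mcl_cluster <- function(net, inflation = 2, expansion = 2, max_iter = 100,
                        tol = 1e-6, prune = 1e-5) {
  stopifnot(inherits(net, "mirna_network"))
  ids <- net$nodes$mirna_id
  n <- length(ids)
  if (n == 0L) {
    return(structure(list(clusters = list(),
                          membership = setNames(integer(0), character(0)),
                          converged = TRUE, iterations = 0L, net = net),
                     class = "mcl_clustering"))
  }
  A <- adjacency_matrix(net)
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- matrix_power(M, expansion)
    Inf_ <- E^inflation
    Inf_[Inf_ < prune] <- 0
    cs <- colSums(Inf_)
    dead <- cs == 0
    if (any(dead)) {            # pruning emptied a column; restore self flow
      Inf_[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mn <- sweep(Inf_, 2L, cs, "/")
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge within %d iterations", max_iter))
  }
  membership <- interpret_attractors(M, ids)
  clusters <- split(names(membership), membership)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) min(cl), character(1)))
  clusters <- unname(lapply(clusters[ord], sort))
  membership <- setNames(rep(seq_along(clusters), lengths(clusters)),
                         unlist(clusters))
  membership <- membership[ids]
  structure(list(clusters = clusters, membership = membership,
                 converged = converged, iterations = it, net = net),
            class = "mcl_clustering")
}

matrix_power <- function(M, p) {
  out <- M
  for (i in seq_len(p - 1L)) out <- out %*% M
  out
}

# Attractors are rows holding diagonal mass in the limit matrix; each node
# (column) is assigned to the attractor row giving it the most flow. Attractor
# rows that share nodes are merged (overlapping attractor systems).
interpret_attractors <- function(M, ids) {
  n <- length(ids)
  attractors <- which(diag(M) > 1e-8)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  owner <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[attractors, j]
    owner[j] <- attractors[which.max(mass)]   # ties: first (lowest) attractor
  }
  # merge attractors connected through shared steady-state support
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in attractors) {
    sup <- which(M[a, ] > 1e-8)
    for (s in sup) parent[find(s)] <- find(a)
  }
  comp <- vapply(owner, find, integer(1))
  setNames(match(comp, unique(comp)), ids)
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters over %d nodes (%s after %d iterations)\n",
              length(x$clusters), length(x$membership),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  sz <- lengths(x$clusters)
  if (length(sz)) cat("  sizes:", paste(sz, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster report: dominant pathways and strongest edges
#'
#' For one cluster, ranks shared features by the number of intra-cluster
#' edges carrying them (the pathways that "make" the cluster), and lists the
#' maximal-weight ("thick") intra-cluster edges.
#'
#' @param clustering `"mcl_clustering"` object.
#' @param cluster_id index of the cluster to report on.
#' @return list with `members` (with direction, if known), `intra_edges`
#'   (data.frame), `dominant_features` (data.frame `feature_id`, `n_edges`),
#'   and `max_weight_edges` (data.frame of edges attaining the maximum
#'   weight; zero rows for singleton clusters).
#' @export
cluster_summary <- function(clustering, cluster_id) {
  stopifnot(inherits(clustering, "mcl_clustering"))
  members <- clustering$clusters[[cluster_id]]
  net <- clustering$net
  in_cl <- net$edges$mirna_a %in% members & net$edges$mirna_b %in% members
  intra <- net$edges[in_cl, , drop = FALSE]
  rownames(intra) <- NULL
  feats <- unlist(net$shared_sets[in_cl], use.names = FALSE)
  dom <- if (length(feats)) {
    tab <- sort(table(feats), decreasing = TRUE)
    data.frame(feature_id = names(tab), n_edges = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(0), n_edges = integer(0))
  }
  mx <- if (nrow(intra)) intra[intra$weight == max(intra$weight), , drop = FALSE] else intra
  rownames(mx) <- NULL
  dirs <- net$nodes$direction[match(members, net$nodes$mirna_id)]
  list(members = data.frame(mirna_id = members, direction = dirs,
                            stringsAsFactors = FALSE),
       intra_edges = intra, dominant_features = dom, max_weight_edges = mx)
}
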