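# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: combinatorial sums instead of phyper, a dense
# reference MCL written separately from the package's pruned implementation,
# and a hand-rolled BH step-up instead of p.adjust.

# Exact hypergeometric upper tail by direct combinatorial summation.
# choose() on integers this small is exact in double precision.
ref_pair_p <- function(N, n, m, x) {
  if (x == 0) return(1)
  s <- 0
  for (i in 0:(x - 1)) {
    if (n - i > N - m) next  # impossible draw, term is zero
    s <- s + choose(m, i) * choose(N - m, n - i)
  }
  1 - s / choose(N, n)
}

# Hypergeometric upper tail by exhaustive enumeration of draws (tiny cases).
ref_ora_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Hand-rolled Benjamini-Hochberg step-up.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Reference MCL: dense, no pruning, clusters read off as connected components
# of the limit matrix's support. Takes a plain weighted adjacency matrix.
ref_mcl <- function(A, inflation = 2, max_iter = 200, tol = 1e-10) {
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mn <- M %*% M
    Mn <- Mn^inflation
    Mn <- sweep(Mn, 2, colSums(Mn), "/")
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  sup <- (M > 1e-6) | t(M > 1e-6)
  g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected")
  igraph::components(g)$membership
}

# Small weighted network object straight from an edge data.frame.
toy_network <- function(edges, mode = "pathway", N = 400) {
  edges$p_value <- if (is.null(edges$p_value)) 0.001 else edges$p_value
  edges$shared_features <- if (is.null(edges$shared_features)) "" else edges$shared_features
  network_from_edges(edges, mode = mode, N = N)
}

# Random connected-ish weighted graph as an edge data.frame.
random_edges <- function(n_nodes, p = 0.2, w_max = 5) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  ea <- character(0); eb <- character(0); w <- integer(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p) {
        ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
        w <- c(w, sample.int(w_max, 1))
      }
    }
  }
  data.frame(mirna_a = ea, mirna_b = eb, weight = w,
             p_value = 0.001, shared_features = "",
             stringsAsFactors = FALSE)
}

adjacency_from_edges <- function(edges) {
  ids <- sort(unique(c(edges$mirna_a, edges$mirna_b)))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    A[edges$mirna_a[i], edges$mirna_b[i]] <- edges$weight[i]
    A[edges$mirna_b[i], edges$mirna_a[i]] <- edges$weight[i]
  }
  A
}
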