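# Readers/writers for the pipeline's plain-text formats: TSV tables and
# matrices, GMT gene-set files (Broad dialect), SIF edge exports for
# Cytoscape. All tables are tab-separated with a header row; identifiers are
# opaque case-sensitive strings.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write a signal-intensity matrix
#'
#' The matrix TSV has a header row of sample ids and a first column of miRNA
#' ids. Non-numeric intensity cells raise an error naming the offending cell.
#'
#' @param path file path.
#' @return numeric matrix with miRNA rownames and sample colnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >= 1 sample")
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric intensity at row %d ('%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' @rdname read_tsv_matrix
#' @param mat numeric matrix with dimnames.
#' @export
write_tsv_matrix <- function(mat, path) {
  df <- data.frame(mirna_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write GMT gene-set files
#'
#' Standard Broad dialect: one set per line, `set_id <tab> description <tab>
#' gene1 <tab> gene2 ...`. On write, gene lists are emitted sorted (the
#' package's canonical form).
#'
#' @param path file path.
#' @return named list of gene-id vectors with a `pathway_names` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT record at line %d (need id, description, >=1 gene)",
                 bad[1]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT file")
  db <- lapply(parts, function(p) p[-(1:2)])
  names(db) <- ids
  attr(db, "pathway_names") <- setNames(vapply(parts, `[[`, character(1), 2L), ids)
  db
}

#' @rdname read_gmt
#' @param db named list of gene vectors, optional `pathway_names` attribute.
#' @export
write_gmt <- function(db, path) {
  nm <- attr(db, "pathway_names")
  if (is.null(nm)) nm <- setNames(names(db), names(db))
  lines <- vapply(names(db), function(id) {
    paste(c(id, nm[[id]], sort(db[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list written by the pipeline
#'
#' @param path edge-list TSV (`mirna_a`, `mirna_b`, `weight`, `p_value`,
#'   `shared_features` semicolon-joined).
#' @return data.frame.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path)
  needed <- c("mirna_a", "mirna_b", "weight", "p_value", "shared_features")
  if (!all(needed %in% names(df))) {
    stop("edge list missing required columns")
  }
  df
}

#' Write a SIF file for Cytoscape import
#'
#' One line per edge: `mirna_a <tab> relation <tab> mirna_b`.
#'
#' @param edges edge data.frame with `mirna_a`, `mirna_b`.
#' @param path output path.
#' @param relation relation label (default `"shares_pathway"`).
#' @export
write_sif <- function(edges, path, relation = "shares_pathway") {
  lines <- sprintf("%s\t%s\t%s", edges$mirna_a, relation, edges$mirna_b)
  writeLines(lines, path)
  invisible(path)
}

#' Reconstruct a network object from an edge list
#'
#' Inverse of the pipeline's edge-list export (modulo isolated nodes, which
#' an edge list cannot carry).
#'
#' @param edges data.frame from [read_edge_list()].
#' @param mode,N,alpha network metadata (see [build_network()]).
#' @param direction optional named direction vector.
#' @return `"mirna_network"` object.
#' @export
network_from_edges <- function(edges, mode = "pathway", N = 400, alpha = 0.05,
                               direction = NULL) {
  node_ids <- sort(unique(c(edges$mirna_a, edges$mirna_b)))
  dir_col <- if (is.null(direction)) rep(NA_character_, length(node_ids)) else
    unname(direction[node_ids])
  structure(list(
    edges = edges[, c("mirna_a", "mirna_b", "weight", "p_value",
                      "shared_features")],
    shared_sets = strsplit(edges$shared_features, ";", fixed = TRUE),
    nodes = data.frame(mirna_id = node_ids, direction = dir_col,
                       stringsAsFactors = FALSE),
    isolated = character(0), mode = mode, N = N, alpha = alpha
  ), class = "mirna_network")
}
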