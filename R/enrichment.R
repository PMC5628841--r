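# Per-miRNA pathway over-representation analysis (ORA) of consensus target
# sets against a fixed gene universe, hypergeometric upper tail, BH-adjusted
# p reported alongside. Significance is declared on the raw p by default.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= overlap_k) for X ~ Hypergeometric drawing
#' `n_targets` genes from a universe of `universe` genes of which
#' `pathway_size` belong to the pathway.
#'
#' @param overlap_k observed overlap between target set and pathway.
#' @param pathway_size number of pathway genes in the universe.
#' @param n_targets size of the target gene set.
#' @param universe total number of genes in the reference universe.
#' @return upper-tail p-value (vectorised over `overlap_k`).
#' @export
ora_pvalue <- function(overlap_k, pathway_size, n_targets, universe) {
  if (any(overlap_k < 0) || pathway_size < 0 || n_targets < 0 || universe < 1) {
    stop("ora_pvalue: counts must be non-negative, universe positive")
  }
  if (pathway_size > universe || n_targets > universe) {
    stop("ora_pvalue: pathway_size and n_targets cannot exceed the universe")
  }
  if (any(overlap_k > pmin(pathway_size, n_targets))) {
    stop("ora_pvalue: overlap exceeds min(pathway_size, n_targets)")
  }
  stats::phyper(overlap_k - 1, pathway_size, universe - pathway_size,
                n_targets, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment with cumulative-minimum monotonization,
#' capped at 1; input order is restored on return.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway enrichment of one miRNA's target set
#'
#' For every pathway overlapping the target set in at least `min_genes` genes,
#' computes the hypergeometric upper-tail p against a fixed universe and the
#' BH-adjusted p over the tested pathways. Records with raw p below `alpha`
#' are flagged significant (set `use_adjusted = TRUE` to flag on adjusted p).
#' Target genes absent from the pathway collection still count toward the
#' target-set size.
#'
#' @param targets character vector of target gene ids (non-empty unless the
#'   caller accepts an empty result).
#' @param db pathway database: named list of character gene vectors, names =
#'   pathway ids; optionally carries a `pathway_names` attribute (named
#'   character vector of descriptions).
#' @param universe reference universe size (default 28000).
#' @param min_genes minimum overlap for a pathway to be considered (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param use_adjusted flag significance on BH-adjusted p instead of raw p.
#' @return data.frame with columns `pathway_id`, `pathway_name`, `overlap_k`,
#'   `pathway_size`, `p_value`, `adj_p`, `significant`; zero rows if nothing
#'   overlaps in >= `min_genes` genes.
#' @export
enrich_mirna <- function(targets, db, universe = 28000, min_genes = 2,
                         alpha = 0.05, use_adjusted = FALSE) {
  if (length(targets) == 0L) {
    return(empty_enrichment())
  }
  targets <- unique(targets)
  sizes <- lengths(db)
  if (any(sizes == 0L)) stop("pathway database contains an empty gene set")
  if (max(sizes) > universe) stop("a pathway exceeds the gene universe")
  overlap <- vapply(db, function(g) length(intersect(targets, g)), integer(1))
  keep <- overlap >= min_genes
  if (!any(keep)) return(empty_enrichment())
  ids <- names(db)[keep]
  k <- overlap[keep]
  K <- sizes[keep]
  n <- length(targets)
  # overlap can exceed what the universe nominally allows only if target ids
  # fall outside the collection's universe; counts stay as observed.
  p <- mapply(function(kk, KK) ora_pvalue(kk, KK, min(n, universe), universe), k, K)
  adj <- bh_adjust(p)
  nm <- attr(db, "pathway_names")
  data.frame(
    pathway_id = ids,
    pathway_name = if (is.null(nm)) ids else unname(nm[ids]),
    overlap_k = unname(k),
    pathway_size = unname(K),
    p_value = unname(p),
    adj_p = unname(adj),
    significant = unname(if (use_adjusted) adj < alpha else p < alpha),
    stringsAsFactors = FALSE
  )
}

empty_enrichment <- function() {
  data.frame(pathway_id = character(0), pathway_name = character(0),
             overlap_k = integer(0), pathway_size = integer(0),
             p_value = numeric(0), adj_p = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' Enrichment across many miRNAs
#'
#' Runs [enrich_mirna()] for every consensus target set and stacks the
#' per-miRNA tables.
#'
#' @param consensus_sets named list: miRNA id -> gene id vector.
#' @inheritParams enrich_mirna
#' @return list with `table` (stacked data.frame with leading `mirna_id`
#'   column) and `enriched` (named list: miRNA id -> significant pathway ids).
#' @export
enrich_all <- function(consensus_sets, db, universe = 28000, min_genes = 2,
                       alpha = 0.05, use_adjusted = FALSE) {
  per <- lapply(consensus_sets, enrich_mirna, db = db, universe = universe,
                min_genes = min_genes, alpha = alpha,
                use_adjusted = use_adjusted)
  tabs <- lapply(names(per), function(m) {
    t <- per[[m]]
    if (nrow(t) == 0L) return(NULL)
    cbind(data.frame(mirna_id = m, stringsAsFactors = FALSE), t)
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  table <- if (length(tabs)) do.call(rbind, tabs) else
    cbind(data.frame(mirna_id = character(0)), empty_enrichment())
  rownames(table) <- NULL
  enriched <- lapply(per, function(t) t$pathway_id[t$significant])
  list(table = table, enriched = enriched)
}
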