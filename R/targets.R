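# Consensus target sets: intersect a rank-based predictor (keep the top k)
# with a score-based predictor (keep scores >= a cut-off), per miRNA.

check_prediction_table <- function(table) {
  needed <- c("mirna_id", "gene_id", "score")
  if (!all(needed %in% names(table))) {
    stop("prediction table needs columns mirna_id, gene_id, score")
  }
  if (anyNA(table$score) || any(!is.finite(table$score))) {
    stop("prediction scores must be finite")
  }
  if (anyDuplicated(table[c("mirna_id", "gene_id")])) {
    stop("duplicate (mirna_id, gene_id) rows in prediction table")
  }
  invisible(TRUE)
}

#' Top-k predicted targets of one miRNA
#'
#' Returns the k genes with the strongest (largest) scores. Ties spanning the
#' rank-k boundary are all included, so the set can exceed k; this keeps the
#' result independent of input row order. A miRNA absent from the table yields
#' an empty set with a warning (such miRNAs are omitted downstream).
#'
#' @param table prediction data.frame (`mirna_id`, `gene_id`, `score`).
#' @param mirna_id single miRNA identifier.
#' @param k number of targets to keep (default 200).
#' @return character vector of gene ids.
#' @export
top_k_targets <- function(table, mirna_id, k = 200) {
  check_prediction_table(table)
  sub <- table[table$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("miRNA '%s' absent from prediction table", mirna_id))
    return(character(0))
  }
  if (nrow(sub) <= k) return(unique(sub$gene_id))
  cut <- sort(sub$score, decreasing = TRUE)[k]
  unique(sub$gene_id[sub$score >= cut])
}

#' Score-thresholded predicted targets of one miRNA
#'
#' Keeps genes whose prediction score is at least `min_score` (inclusive
#' boundary). A miRNA absent from the table yields an empty set with a warning.
#'
#' @inheritParams top_k_targets
#' @param min_score inclusive score cut-off (default 0.7).
#' @return character vector of gene ids.
#' @export
score_cut_targets <- function(table, mirna_id, min_score = 0.7) {
  check_prediction_table(table)
  sub <- table[table$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("miRNA '%s' absent from prediction table", mirna_id))
    return(character(0))
  }
  unique(sub$gene_id[sub$score >= min_score])
}

#' Consensus of two predicted target sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return their intersection.
#' @export
consensus <- function(set_a, set_b) intersect(set_a, set_b)

#' Consensus target sets for a list of miRNAs
#'
#' For each miRNA, intersects the top-`k` targets of the rank-based source
#' with the score-thresholded targets of the score-based source. miRNAs with
#' an empty consensus are retained in the returned list as empty sets; callers
#' drop them via [omit_unsupported()].
#'
#' @param pred_a rank-based prediction table (larger score = stronger).
#' @param pred_b score-based prediction table (scores in \[0,1\]).
#' @param mirna_ids miRNAs to process (default: union of both tables).
#' @param top_k,min_score cut-offs for the two sources.
#' @return named list: miRNA id -> character vector of consensus gene ids.
#' @export
consensus_targets <- function(pred_a, pred_b, mirna_ids = NULL,
                              top_k = 200, min_score = 0.7) {
  check_prediction_table(pred_a)
  check_prediction_table(pred_b)
  if (any(pred_b$score < 0 | pred_b$score > 1)) {
    stop("score-based source must have scores in [0, 1]")
  }
  if (is.null(mirna_ids)) {
    mirna_ids <- sort(union(unique(pred_a$mirna_id), unique(pred_b$mirna_id)))
  }
  out <- lapply(mirna_ids, function(m) {
    a <- suppressWarnings(top_k_targets(pred_a, m, k = top_k))
    b <- suppressWarnings(score_cut_targets(pred_b, m, min_score = min_score))
    consensus(a, b)
  })
  names(out) <- mirna_ids
  out
}

#' Final miRNA list after support filtering
#'
#' A responsive miRNA enters the network only if it has (i) a non-empty
#' consensus target set and (ii) at least one enriched pathway. Everything
#' else is omitted, with the reason recorded.
#'
#' @param responsive character vector of responsive miRNA ids.
#' @param consensus_sets named list from [consensus_targets()].
#' @param enriched named list: miRNA id -> character vector of significantly
#'   enriched feature ids (may be missing or empty for unsupported miRNAs).
#' @return list with `final` (character vector), `omitted` (data.frame of
#'   `mirna_id`, `reason` in \{"no_overlap", "no_enrichment"\}), and
#'   `n_omitted`.
#' @export
omit_unsupported <- function(responsive, consensus_sets, enriched) {
  has_targets <- vapply(responsive, function(m) {
    length(consensus_sets[[m]]) > 0
  }, logical(1))
  has_enrich <- vapply(responsive, function(m) {
    length(enriched[[m]]) > 0
  }, logical(1))
  final <- responsive[has_targets & has_enrich]
  omit <- responsive[!(has_targets & has_enrich)]
  reason <- ifelse(!has_targets[match(omit, responsive)], "no_overlap", "no_enrichment")
  list(
    final = final,
    omitted = data.frame(mirna_id = omit, reason = reason,
                         stringsAsFactors = FALSE),
    n_omitted = length(omit)
  )
}
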