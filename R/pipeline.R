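# End-to-end driver: one fitting function assembling every stage into a
# classed result, plus a file-based pipeline writing each stage's output.

#' Fit the pathway-based miRNA-miRNA network pipeline
#'
#' Runs the full analysis from in-memory inputs: quantile normalization and
#' responsive-miRNA calling, consensus target prediction, per-miRNA pathway
#' over-representation, support filtering, pair-overlap network construction,
#' degree centrality, most-targeted-gene tally, and MCL clustering of the
#' weight-thresholded network.
#'
#' @param mat positive miRNA x sample intensity matrix.
#' @param design data.frame (`sample_id`, `group`).
#' @param pred_a,pred_b the rank-based and score-based prediction tables.
#' @param db pathway database (named list of gene vectors, e.g. from
#'   [read_gmt()]).
#' @param treated,control group labels (defaults "treated"/"control").
#' @param p_cut,fc_cut responsive-calling cut-offs (defaults 0.05, 2).
#' @param test two-sample test variant (default "student").
#' @param top_k,min_score consensus cut-offs (defaults 200, 0.7).
#' @param min_genes,alpha_enrich enrichment parameters (defaults 2, 0.05).
#' @param universe_genes gene-universe size for ORA and gene-mode networks
#'   (default 28000).
#' @param universe_pathways pathway-universe size for pathway-mode pair tests
#'   (default 400; fixed to the size of the reference collection, not to the
#'   number of enriched pathways).
#' @param alpha_pair pair-overlap significance threshold (default 0.05).
#' @param mode link miRNAs by shared enriched `"pathway"`s (default) or
#'   shared consensus target `"gene"`s.
#' @param min_weight MCL edge-weight threshold (default 2.9).
#' @param inflation MCL inflation (default 2).
#' @return object of class `"mirnet"`: list with `differential`,
#'   `responsive`, `consensus`, `enrichment` (stacked table), `enriched`
#'   (per-miRNA significant pathways), `support` (final/omitted lists),
#'   `network`, `centrality`, `summary`, `most_targeted`, `thresholded`,
#'   `clustering`, and `params`.
#' @seealso [simulate_study()] to generate inputs, [run_pipeline()] for the
#'   file-based driver.
#' @export
mirnet <- function(mat, design, pred_a, pred_b, db,
                   treated = "treated", control = "control",
                   p_cut = 0.05, fc_cut = 2, test = "student",
                   top_k = 200, min_score = 0.7,
                   min_genes = 2, alpha_enrich = 0.05,
                   universe_genes = 28000, universe_pathways = 400,
                   alpha_pair = 0.05, mode = c("pathway", "gene"),
                   min_weight = 2.9, inflation = 2) {
  mode <- match.arg(mode)
  params <- list(p_cut = p_cut, fc_cut = fc_cut, test = test, top_k = top_k,
                 min_score = min_score, min_genes = min_genes,
                 alpha_enrich = alpha_enrich, universe_genes = universe_genes,
                 universe_pathways = universe_pathways,
                 alpha_pair = alpha_pair, mode = mode,
                 min_weight = min_weight, inflation = inflation)

  de <- differential_expression(mat, design, treated = treated,
                                control = control, test = test)
  responsive <- call_responsive(de, p_cut = p_cut, fc_cut = fc_cut)
  out <- list(differential = de, responsive = responsive, params = params)
  class(out) <- "mirnet"
  if (nrow(responsive) == 0L) {
    message("no miRNA passed the responsiveness cut-offs; stopping after differential calling")
    return(out)
  }
  direction <- setNames(responsive$direction, responsive$mirna_id)

  cons <- consensus_targets(pred_a, pred_b, mirna_ids = responsive$mirna_id,
                            top_k = top_k, min_score = min_score)
  enr <- enrich_all(cons, db, universe = universe_genes,
                    min_genes = min_genes, alpha = alpha_enrich)
  support <- omit_unsupported(responsive$mirna_id, cons, enr$enriched)
  out$consensus <- cons
  out$enrichment <- enr$table
  out$enriched <- enr$enriched
  out$support <- support
  if (length(support$final) == 0L) {
    message("no responsive miRNA retained both consensus targets and enrichment; stopping before network construction")
    return(out)
  }

  annotations <- if (mode == "pathway") {
    enr$enriched[support$final]
  } else {
    cons[support$final]
  }
  N <- if (mode == "pathway") universe_pathways else universe_genes
  net <- build_network(annotations, N = N, alpha = alpha_pair,
                       direction = direction, mode = mode)
  out$network <- net
  out$centrality <- degree_centrality(net)
  out$summary <- network_summary(net, annotations)
  out$most_targeted <- most_targeted_genes(cons[net$nodes$mirna_id])
  thr <- threshold_edges(net, min_weight = min_weight)
  out$thresholded <- thr
  out$clustering <- mcl_cluster(thr, inflation = inflation)
  out
}

#' @export
print.mirnet <- function(x, ...) {
  cat("Pathway-based miRNA-miRNA network pipeline\n")
  cat(sprintf("  %d miRNAs profiled; %d responsive (p < %g, |FC| > %g)\n",
              nrow(x$differential), nrow(x$responsive),
              x$params$p_cut, x$params$fc_cut))
  if (!is.null(x$support)) {
    cat(sprintf("  %d retained after target/enrichment support (%d omitted)\n",
                length(x$support$final), x$support$n_omitted))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  network (%s mode): %d interacting miRNAs, %d edges\n",
                x$params$mode, nrow(x$network$nodes), nrow(x$network$edges)))
  }
  if (!is.null(x$clustering)) {
    cat(sprintf("  MCL (weight >= %g, inflation %g): %d clusters, sizes %s\n",
                x$params$min_weight, x$params$inflation,
                length(x$clustering$clusters),
                paste(lengths(x$clustering$clusters), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.mirnet <- function(object, n_top = 10, ...) {
  print(object)
  if (!is.null(object$centrality) && nrow(object$centrality)) {
    cat("\nMost central miRNAs (degree):\n")
    print(utils::head(object$centrality, n_top), row.names = FALSE)
  }
  if (!is.null(object$most_targeted) && nrow(object$most_targeted)) {
    cat("\nMost targeted genes:\n")
    print(utils::head(object$most_targeted, n_top), row.names = FALSE)
  }
  invisible(object)
}

#' Plot a fitted miRNA-miRNA network
#'
#' Circular layout; node colour encodes direction (red = up, green = down),
#' node size scales with degree, edge width with weight.
#'
#' @param x `"mirnet"` or `"mirna_network"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirnet <- function(x, ...) {
  if (is.null(x$network) || nrow(x$network$edges) == 0L) {
    stop("nothing to plot: the fitted object has no network edges")
  }
  plot(x$network, ...)
}

#' @export
plot.mirna_network <- function(x, ...) {
  ids <- x$nodes$mirna_id
  n <- length(ids)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xy <- cbind(cos(theta), sin(theta))
  rownames(xy) <- ids
  deg <- degree_centrality(x)
  size <- 1 + 2 * deg$degree[match(ids, deg$mirna_id)] / max(1, max(deg$degree))
  col <- ifelse(is.na(x$nodes$direction), "grey60",
                ifelse(x$nodes$direction == "up", "firebrick", "forestgreen"))
  graphics::plot(xy, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 type = "n", xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), ...)
  for (i in seq_len(nrow(x$edges))) {
    a <- xy[x$edges$mirna_a[i], ]; b <- xy[x$edges$mirna_b[i], ]
    graphics::segments(a[1], a[2], b[1], b[2], col = "grey70",
                       lwd = 0.5 + x$edges$weight[i] / 2)
  }
  graphics::points(xy, pch = 21, bg = col, cex = size)
  graphics::text(xy * 1.15, labels = ids, cex = 0.6)
  invisible(x)
}

#' Run the pipeline from files and write every stage's output
#'
#' File-based front end to [mirnet()]: reads the signal matrix, design,
#' prediction tables and GMT, fits the pipeline, and writes the differential
#' table, consensus sets, omission report, enrichment table, edge list + SIF,
#' node attributes, centrality, network summary, most-targeted genes,
#' cluster assignments, per-cluster reports, and a JSON-like run manifest.
#' Re-running with identical inputs and parameters reproduces identical
#' outputs (every stage is deterministic).
#'
#' @param matrix_path,design_path,pred_a_path,pred_b_path,gmt_path input
#'   files in the formats written by [write_simulation()].
#' @param outdir output directory.
#' @param ... pipeline parameters passed to [mirnet()].
#' @return the fitted `"mirnet"` object, invisibly; outputs on disk.
#' @export
run_pipeline <- function(matrix_path, design_path, pred_a_path, pred_b_path,
                         gmt_path, outdir, ...) {
  mat <- read_tsv_matrix(matrix_path)
  design <- read_tsv(design_path)
  pred_a <- read_tsv(pred_a_path)
  pred_b <- read_tsv(pred_b_path)
  db <- read_gmt(gmt_path)
  fit <- mirnet(mat, design, pred_a, pred_b, db, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  write_tsv(round_cols(fit$differential, c(gmean_treated = 2, gmean_control = 2,
                                           fold_change = 2)),
            file.path(outdir, "differential.tsv"))
  counts$differential <- nrow(fit$differential)
  write_tsv(round_cols(fit$responsive, c(gmean_treated = 2, gmean_control = 2,
                                         fold_change = 2)),
            file.path(outdir, "responsive.tsv"))
  counts$responsive <- nrow(fit$responsive)

  if (!is.null(fit$consensus)) {
    cons_df <- data.frame(
      mirna_id = rep(names(fit$consensus), lengths(fit$consensus)),
      gene_id = unlist(fit$consensus, use.names = FALSE),
      stringsAsFactors = FALSE)
    write_tsv(cons_df, file.path(outdir, "consensus_targets.tsv"))
    counts$consensus_pairs <- nrow(cons_df)
    write_tsv(fit$support$omitted, file.path(outdir, "omitted.tsv"))
    counts$omitted <- nrow(fit$support$omitted)
    write_tsv(fit$enrichment, file.path(outdir, "enrichment.tsv"))
    counts$enrichment <- nrow(fit$enrichment)
  }
  if (!is.null(fit$network)) {
    write_tsv(fit$network$edges, file.path(outdir, "edges.tsv"))
    counts$edges <- nrow(fit$network$edges)
    write_sif(fit$network$edges, file.path(outdir, "network.sif"),
              relation = paste0("shares_", fit$params$mode))
    write_tsv(fit$centrality, file.path(outdir, "centrality.tsv"))
    write_tsv(fit$summary, file.path(outdir, "network_summary.tsv"))
    write_tsv(fit$most_targeted, file.path(outdir, "most_targeted_genes.tsv"))
    counts$network_nodes <- nrow(fit$network$nodes)
  }
  if (!is.null(fit$clustering)) {
    cl <- fit$clustering
    cl_df <- data.frame(
      cluster_id = rep(seq_along(cl$clusters), lengths(cl$clusters)),
      mirna_id = unlist(cl$clusters, use.names = FALSE),
      stringsAsFactors = FALSE)
    cl_df$direction <- fit$thresholded$nodes$direction[
      match(cl_df$mirna_id, fit$thresholded$nodes$mirna_id)]
    write_tsv(cl_df, file.path(outdir, "clusters.tsv"))
    counts$clusters <- length(cl$clusters)
    reports <- lapply(seq_along(cl$clusters), function(i) {
      s <- cluster_summary(cl, i)
      data.frame(cluster_id = i, size = nrow(s$members),
                 dominant_features = paste(utils::head(s$dominant_features$feature_id, 5),
                                           collapse = ";"),
                 max_weight = if (nrow(s$max_weight_edges)) max(s$max_weight_edges$weight) else NA,
                 stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, reports), file.path(outdir, "cluster_report.tsv"))
  }
  manifest <- c(
    list(package_version = as.character(utils::packageVersion("mirnet")),
         parameters = fit$params,
         inputs = as.list(c(matrix = matrix_path, design = design_path,
                            pred_a = pred_a_path, pred_b = pred_b_path,
                            gmt = gmt_path)),
         input_md5 = as.list(unname_to_base(tools::md5sum(
           c(matrix_path, design_path, pred_a_path, pred_b_path, gmt_path))))),
    list(record_counts = counts)
  )
  writeLines(manifest_json(manifest), file.path(outdir, "manifest.json"))
  invisible(fit)
}

unname_to_base <- function(x) setNames(as.character(x), basename(names(x)))

round_cols <- function(df, digits) {
  for (nm in names(digits)) if (nm %in% names(df)) df[[nm]] <- round(df[[nm]], digits[[nm]])
  df
}

# minimal JSON emitter for the manifest (scalars, flat lists, named lists)
manifest_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    items <- vapply(names(x), function(nm) {
      sprintf("%s  \"%s\": %s", pad, nm,
              sub("^\\s+", "", manifest_json(x[[nm]], indent + 2)))
    }, character(1))
    paste0(pad, "{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
  } else if (length(x) == 1L) {
    if (is.character(x)) sprintf("%s\"%s\"", pad, x) else paste0(pad, format(x, digits = 15))
  } else {
    vals <- if (is.character(x)) sprintf("\"%s\"", x) else format(x, digits = 15)
    paste0(pad, "[", paste(vals, collapse = ", "), "]")
  }
}
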