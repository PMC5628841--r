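# Seeded synthetic inputs with planted ground truth: an Agilent-style miRNA
# intensity matrix with a planted responsive subset, two target-prediction
# sources with controlled agreement, and a KEGG-like pathway collection with
# planted blocks of miRNAs sharing pathways. Everything downstream of the
# generator is testable against the planted truth without any download.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator. The
#' defaults emulate the profiled array and reference collections of a
#' two-replicate trastuzumab-vs-PBS miRNA experiment: 2006 miRNAs, 2
#' biological replicates per group, a 28000-gene universe and 400 pathways.
#'
#' @param n_mirnas number of miRNAs on the array (default 2006).
#' @param n_replicates_per_group biological replicates per group (default 2).
#' @param n_responsive planted differential miRNAs (default 200).
#' @param planted_log2fc planted effect size in log2 units (default 2, i.e.
#'   4-fold; must give |FC| >= 2).
#' @param intensity_location,intensity_scale mean and sd of the log2 baseline
#'   intensity across miRNAs (defaults 7 and 2: positive skewed intensities
#'   on the natural scale, median around 128).
#' @param noise_sd i.i.d. replicate noise sd in log2 units (default 0.25).
#' @param n_genes gene-universe size (default 28000).
#' @param n_pathways number of pathway gene sets (default 400).
#' @param pathway_size_range min/max genes per pathway (default c(20, 200)).
#' @param n_blocks planted miRNA modules sharing pathways (default 2).
#' @param block_size miRNAs per planted block (default: 10, shrunk to fit
#'   when `n_responsive` is small); blocks are drawn from the planted
#'   responsive miRNAs, so an explicit `n_blocks * block_size` must not
#'   exceed `n_responsive`.
#' @param pathways_per_block pathways assigned to each block (default 8;
#'   blocks get disjoint pathway subsets).
#' @param genes_per_block_pathway block-pathway genes planted into each block
#'   member's target set (default 5).
#' @param n_background_targets non-pathway-driven targets per responsive
#'   miRNA (default 60).
#' @param source_agreement fraction in \[0,1\] of truth targets recovered by
#'   the consensus of the two prediction sources (default 0.9).
#' @param hub_gene_mirnas if positive, a designated hub gene (`"GHUB"`) is
#'   planted into this many responsive miRNAs' target sets (default 0).
#' @param seed integer random seed.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_mirnas = 2006, n_replicates_per_group = 2,
                       n_responsive = 200, planted_log2fc = 2,
                       intensity_location = 7, intensity_scale = 2,
                       noise_sd = 0.25, n_genes = 28000, n_pathways = 400,
                       pathway_size_range = c(20, 200), n_blocks = 2,
                       block_size = NULL, pathways_per_block = 8,
                       genes_per_block_pathway = 5, n_background_targets = 60,
                       source_agreement = 0.9, hub_gene_mirnas = 0,
                       seed = 1) {
  if (is.null(block_size)) {
    block_size <- if (n_blocks > 0) min(10, n_responsive %/% n_blocks) else 0
    if (block_size == 0) n_blocks <- 0
  }
  cfg <- list(n_mirnas = n_mirnas,
              n_replicates_per_group = n_replicates_per_group,
              n_responsive = n_responsive, planted_log2fc = planted_log2fc,
              intensity_location = intensity_location,
              intensity_scale = intensity_scale, noise_sd = noise_sd,
              n_genes = n_genes, n_pathways = n_pathways,
              pathway_size_range = pathway_size_range, n_blocks = n_blocks,
              block_size = block_size, pathways_per_block = pathways_per_block,
              genes_per_block_pathway = genes_per_block_pathway,
              n_background_targets = n_background_targets,
              source_agreement = source_agreement,
              hub_gene_mirnas = hub_gene_mirnas, seed = seed)
  for (f in c("n_mirnas", "n_replicates_per_group", "n_genes", "n_pathways")) {
    if (cfg[[f]] < 1) stop(sprintf("config field '%s' must be positive", f))
  }
  if (n_responsive < 0 || n_responsive > n_mirnas) {
    stop("config field 'n_responsive' must lie in [0, n_mirnas]")
  }
  if (source_agreement < 0 || source_agreement > 1) {
    stop("config field 'source_agreement' must lie in [0, 1]")
  }
  if (planted_log2fc < 1) {
    stop("config field 'planted_log2fc' must be >= 1 (|FC| >= 2)")
  }
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[2] > n_genes) {
    stop("config field 'pathway_size_range' must be c(min, max) within the gene universe")
  }
  if (n_blocks * block_size > max(n_responsive, 0)) {
    stop("config fields 'n_blocks' * 'block_size' exceed 'n_responsive'")
  }
  if (n_blocks * pathways_per_block > n_pathways) {
    stop("config field 'pathways_per_block' exceeds the pathway collection")
  }
  if (noise_sd <= 0 || intensity_scale < 0) {
    stop("config fields 'noise_sd'/'intensity_scale' must be positive")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic sub-stream per output: every simulate_* call reseeds from the
# config seed plus a fixed offset, so components are reproducible in isolation
# and in any order.
with_sim_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((config$seed * 7L + offset) %% .Machine$integer.max)
  expr
}

mirna_ids <- function(n) sprintf("mir-%04d", seq_len(n))
gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate the miRNA signal-intensity matrix
#'
#' Each miRNA gets a log2 baseline drawn from
#' N(`intensity_location`, `intensity_scale`); planted responsive miRNAs are
#' shifted by +/- `planted_log2fc`/2 in the treated and control groups
#' (random sign per miRNA), and i.i.d. replicate noise of sd `noise_sd` is
#' added per sample. Intensities are returned on the natural scale (2^x), so
#' they are strictly positive and positively skewed.
#'
#' @param config `"sim_config"` object.
#' @return list with `matrix` (n_mirnas x 2*n_replicates), `design`
#'   (data.frame `sample_id`, `group` in \{treated, control\}), and `truth`
#'   (data.frame `mirna_id`, `true_log2fc`, `direction` for every planted
#'   miRNA; zero rows when `n_responsive = 0`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 11L, {
    n <- config$n_mirnas
    r <- config$n_replicates_per_group
    ids <- mirna_ids(n)
    planted <- if (config$n_responsive > 0) {
      sort(sample.int(n, config$n_responsive))
    } else integer(0)
    sign_ <- sample(c(1, -1), length(planted), replace = TRUE)
    base <- stats::rnorm(n, config$intensity_location, config$intensity_scale)
    shift <- numeric(n)
    shift[planted] <- sign_ * config$planted_log2fc / 2
    samples <- c(sprintf("treated_%d", seq_len(r)),
                 sprintf("control_%d", seq_len(r)))
    grp <- rep(c("treated", "control"), each = r)
    mu <- outer(base, rep(1, 2 * r)) +
      outer(shift, ifelse(grp == "treated", 1, -1))
    mat <- 2^(mu + matrix(stats::rnorm(n * 2 * r, 0, config$noise_sd), n, 2 * r))
    dimnames(mat) <- list(ids, samples)
    list(
      matrix = mat,
      design = data.frame(sample_id = samples, group = grp,
                          stringsAsFactors = FALSE),
      truth = data.frame(mirna_id = ids[planted],
                         true_log2fc = sign_ * config$planted_log2fc,
                         direction = ifelse(sign_ > 0, "up", "down"),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate the pathway collection and planted block structure
#'
#' Draws `n_pathways` gene sets from the gene universe with sizes uniform in
#' `pathway_size_range`. The first `n_blocks * pathways_per_block` pathways
#' are reserved as planted block pathways: block b owns a disjoint subset of
#' `pathways_per_block` pathways, and [simulate_targets()] gives every miRNA
#' of block b target genes drawn from those pathways, so block members share
#' the same enriched pathways and the downstream network recovers the blocks.
#'
#' @param config `"sim_config"` object.
#' @return list with `db` (named list pathway_id -> gene vector, with a
#'   `pathway_names` attribute) and `block_pathways` (list: block index ->
#'   pathway ids).
#' @export
simulate_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 23L, {
    genes <- gene_ids(config$n_genes)
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    ids <- sprintf("path%04d", seq_len(config$n_pathways))
    db <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(db) <- ids
    attr(db, "pathway_names") <- setNames(sprintf("synthetic pathway %s", ids), ids)
    nb <- config$n_blocks * config$pathways_per_block
    block_pathways <- if (config$n_blocks > 0 && nb > 0) {
      split(ids[seq_len(nb)],
            rep(seq_len(config$n_blocks), each = config$pathways_per_block))
    } else list()
    list(db = db, block_pathways = block_pathways)
  })
}

#' Simulate planted truth target sets
#'
#' The first `n_blocks * block_size` planted responsive miRNAs form the
#' blocks; each block member's truth target set contains
#' `genes_per_block_pathway` genes from every one of its block's pathways
#' plus `n_background_targets` genes drawn from the rest of the universe.
#' Non-block responsive miRNAs get background targets only. When
#' `hub_gene_mirnas > 0` the designated hub gene `"GHUB"` is appended to that
#' many responsive miRNAs' sets.
#'
#' @param config `"sim_config"` object.
#' @param truth truth table from [simulate_expression()].
#' @param pathways result of [simulate_pathways()].
#' @return list with `targets` (named list mirna_id -> gene vector) and
#'   `blocks` (data.frame `mirna_id`, `block`; block NA for non-block
#'   responsive miRNAs).
#' @export
simulate_targets <- function(config, truth, pathways) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 37L, {
    mirnas <- truth$mirna_id
    genes <- gene_ids(config$n_genes)
    block_of <- rep(NA_integer_, length(mirnas))
    nb <- config$n_blocks * config$block_size
    if (nb > 0) block_of[seq_len(nb)] <- rep(seq_len(config$n_blocks),
                                             each = config$block_size)
    targets <- vector("list", length(mirnas))
    names(targets) <- mirnas
    for (i in seq_along(mirnas)) {
      tg <- character(0)
      if (!is.na(block_of[i])) {
        for (p in pathways$block_pathways[[block_of[i]]]) {
          tg <- c(tg, sample(pathways$db[[p]],
                             min(config$genes_per_block_pathway,
                                 length(pathways$db[[p]]))))
        }
      }
      tg <- c(tg, sample(genes, config$n_background_targets))
      targets[[i]] <- sort(unique(tg))
    }
    if (config$hub_gene_mirnas > 0) {
      hub_in <- seq_len(min(config$hub_gene_mirnas, length(mirnas)))
      for (i in hub_in) targets[[i]] <- sort(unique(c(targets[[i]], "GHUB")))
    }
    list(targets = targets,
         blocks = data.frame(mirna_id = mirnas, block = block_of,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate the two prediction sources
#'
#' Source A mimics a rank-scored predictor (arbitrary positive scores,
#' larger = stronger): every truth target appears within the top-`top_k`
#' scores, padded with distractor genes below them. Source B mimics a
#' \[0,1\]-scored predictor: each truth target passes the `min_score` cut-off
#' with probability `source_agreement` (Beta-distributed scores shifted above
#' the cut-off), the rest fall below it, and distractors get sub-threshold
#' scores. The consensus of (top-`top_k` of A) and (B >= `min_score`) is the
#' truth set exactly when `source_agreement = 1`, and a Binomial(|truth|,
#' `source_agreement`) thinning of it otherwise.
#'
#' @param config `"sim_config"` object.
#' @param truth_targets named list mirna_id -> truth gene vector.
#' @param top_k,min_score the downstream consensus cut-offs the generator
#'   calibrates to (defaults 200 and 0.7).
#' @param n_distractors distractor predictions per miRNA per source
#'   (default 50).
#' @return list with `pred_a` and `pred_b` (data.frames `mirna_id`,
#'   `gene_id`, `score`, `source`).
#' @export
simulate_predictions <- function(config, truth_targets, top_k = 200,
                                 min_score = 0.7, n_distractors = 50) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(names(truth_targets), mirna_ids(config$n_mirnas))
  if (length(unknown)) {
    stop(sprintf("unknown miRNA id(s) in truth targets: %s",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  }
  with_sim_seed(config, 53L, {
    genes <- gene_ids(config$n_genes)
    rows_a <- list(); rows_b <- list()
    for (m in names(truth_targets)) {
      tg <- truth_targets[[m]]
      nt <- length(tg)
      if (nt > top_k) {
        stop(sprintf("truth set of '%s' exceeds top_k = %d", m, top_k))
      }
      pool <- setdiff(genes, tg)
      dis_a <- sample(pool, min(n_distractors, length(pool)))
      dis_b <- sample(pool, min(n_distractors, length(pool)))
      # A: truth targets occupy the strongest ranks
      score_a <- c(stats::runif(nt, 10, 20), stats::runif(length(dis_a), 0.1, 5))
      rows_a[[m]] <- data.frame(mirna_id = m, gene_id = c(tg, dis_a),
                                score = score_a, source = "A_rank",
                                stringsAsFactors = FALSE)
      # B: truth targets pass the cut-off with prob source_agreement
      pass <- stats::runif(nt) < config$source_agreement
      score_b <- numeric(nt)
      score_b[pass] <- min_score + (1 - min_score) * stats::rbeta(sum(pass), 2, 2)
      score_b[!pass] <- min_score * stats::rbeta(sum(!pass), 2, 2)
      rows_b[[m]] <- data.frame(
        mirna_id = m, gene_id = c(tg, dis_b),
        score = c(score_b, min_score * stats::rbeta(length(dis_b), 2, 2)),
        source = "B_score", stringsAsFactors = FALSE)
    }
    list(pred_a = do.call(rbind, c(rows_a, list(make.row.names = FALSE))),
         pred_b = do.call(rbind, c(rows_b, list(make.row.names = FALSE))))
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_pathways()], [simulate_targets()] and [simulate_predictions()]
#' under one config, returning every input the pipeline needs plus the
#' planted ground truth.
#'
#' @param config `"sim_config"` object.
#' @param top_k,min_score consensus cut-offs the predictions are calibrated
#'   to.
#' @return list with `matrix`, `design`, `truth`, `db`, `block_pathways`,
#'   `truth_targets`, `blocks`, `pred_a`, `pred_b`, `config`.
#' @export
simulate_study <- function(config, top_k = 200, min_score = 0.7) {
  expr <- simulate_expression(config)
  pw <- simulate_pathways(config)
  tg <- simulate_targets(config, expr$truth, pw)
  pred <- simulate_predictions(config, tg$targets, top_k = top_k,
                               min_score = min_score)
  list(matrix = expr$matrix, design = expr$design, truth = expr$truth,
       db = pw$db, block_pathways = pw$block_pathways,
       truth_targets = tg$targets, blocks = tg$blocks,
       pred_a = pred$pred_a, pred_b = pred$pred_b, config = config)
}

#' Write a simulated study to disk
#'
#' Emits the generator's outputs in the pipeline's file formats: signal
#' matrix TSV, design TSV, one prediction TSV per source, pathway GMT, and
#' truth tables.
#'
#' @param study result of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(outdir, "signal_matrix.tsv"),
    design = file.path(outdir, "design.tsv"),
    pred_a = file.path(outdir, "predictions_A.tsv"),
    pred_b = file.path(outdir, "predictions_B.tsv"),
    gmt = file.path(outdir, "pathways.gmt"),
    truth = file.path(outdir, "truth_responsive.tsv"),
    blocks = file.path(outdir, "truth_blocks.tsv")
  )
  write_tsv_matrix(study$matrix, paths["matrix"])
  write_tsv(study$design, paths["design"])
  write_tsv(study$pred_a, paths["pred_a"])
  write_tsv(study$pred_b, paths["pred_b"])
  write_gmt(study$db, paths["gmt"])
  write_tsv(study$truth, paths["truth"])
  write_tsv(study$blocks, paths["blocks"])
  invisible(paths)
}
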