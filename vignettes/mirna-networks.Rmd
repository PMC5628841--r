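---
title: "Pathway-based miRNA-miRNA networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based miRNA-miRNA networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnet)
```

## The model

A single miRNA represses many transcripts, and drug response is rarely
attributable to one miRNA acting alone. `mirnet` represents the *functional
relatedness* of treatment-responsive miRNAs as a homogeneous network: nodes
are miRNAs, and an edge between two miRNAs records the pathways in which both
of their predicted target sets are over-represented. A shared property
(pathways) is used as the connector instead of being materialized as a second
node type, which keeps the graph one-molecule-typed and directly clusterable.

The pipeline has five statistical stages.

1. **Responsive-miRNA calling.** Intensities are quantile-normalized so every
   array shares one intensity distribution, then each miRNA is tested between
   the two groups with a two-sample t statistic on log2 intensities. The fold
   change is computed from the *geometric means* of the normalized, unlogged
   intensities and reported signed: the ratio \(r = \bar g_T/\bar g_C\) if
   \(r \ge 1\), else \(-1/r\), so magnitude is always at least 1 and sign
   encodes direction. Cut-offs: \(p < 0.05\) and \(|FC| > 2\).
2. **Consensus targets.** Two prediction sources are intersected per miRNA:
   the top 200 predictions of a rank-scored source and the predictions of a
   \([0,1]\)-scored source at score \(\ge 0.7\). Intersection trades recall
   for precision, which matters because everything downstream counts set
   overlaps.
3. **Pathway over-representation.** For each miRNA's consensus set of size
   \(n\) against a pathway of size \(K\) in a fixed universe of \(N\) genes
   (default 28000), the upper-tail hypergeometric probability
   \(P(X \ge k)\) is computed; pathways overlapping in fewer than 2 genes are
   never considered. Benjamini–Hochberg adjusted values are reported, but
   significance is declared on the raw \(p < 0.05\) — the criterion the
   pathway counts downstream depend on — with `use_adjusted = TRUE` available
   as the stricter alternative. miRNAs with no consensus targets or no
   enriched pathway are omitted before network construction.
4. **Pair-overlap network.** For every miRNA pair annotated with \(n\) and
   \(m\) enriched pathways sharing \(x\) of them, the edge significance is
   \[P = 1 - \sum_{i=0}^{x-1} \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}},\]
   the chance of sharing at least \(x\) features if each miRNA's feature set
   were a uniform draw from a universe of \(N\) features. In pathway mode
   \(N\) is fixed at the size of the reference collection (400), *not* at the
   number of pathways enriched in the data set: the significance threshold is
   defined against the collection a practitioner queries, and making \(N\)
   data-dependent would move the threshold with the data. Pairs with
   \(p < 0.05\) become edges weighted by \(x\). Pairs sharing nothing are
   never tested (their \(p\) is 1 by construction). Pair p-values are not
   multiplicity-adjusted, matching the raw-\(p\) filtering convention of the
   other stages; up/down direction is carried as a node attribute and never
   influences edge formation, so clusters can and do mix directions.
5. **Degree centrality and MCL clustering.** Node importance is the
   unweighted degree (distinct neighbours). For module detection the network
   is first thresholded at edge weight \(\ge 2.9\) — i.e. pairs must share at
   least three pathways — then clustered with the Markov Cluster algorithm:
   self-loops are added (loop weight = the node's maximum incident edge
   weight, which stabilizes convergence on small graphs), the matrix is made
   column-stochastic, and expansion (matrix squaring) alternates with
   inflation (entry-wise power 2 and renormalization) until the flow matrix
   stabilizes. Attractor rows define clusters; a node attracted to several is
   assigned to the attractor holding the most steady-state mass, ties broken
   toward the lowest cluster id so partitions are reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_cut`, `fc_cut` | 0.05, 2 | responsive-calling cut-offs (raw p; linear fold change) |
| `top_k` | 200 | targets kept from the rank-scored source |
| `min_score` | 0.7 | inclusive cut-off on the \([0,1]\)-scored source |
| `min_genes` | 2 | minimum target–pathway overlap considered in ORA |
| `universe_genes` | 28000 | ORA and gene-mode universe size |
| `universe_pathways` | 400 | pathway-mode pair-test universe |
| `alpha_enrich`, `alpha_pair` | 0.05 | ORA / pair-test significance |
| `min_weight` | 2.9 | MCL edge-weight threshold (integer weights ≥ 3 pass) |
| `inflation` | 2 | MCL granularity; 2 is the canonical default |

Decisions worth spelling out, because the conventions are genuinely open:

* **The 0.7 score cut-off is inclusive** (`score >= 0.7`), the conventional
  reading of a "cut-off value".
* **Rank-boundary ties in top-k are all kept**, so the selected set can
  exceed `k`; the alternative (breaking ties by row order) would make results
  depend on file ordering.
* **The t-test is an ordinary pooled-variance Student's t by default.**
  Moderated class-comparison tests shrink per-feature variances with
  hyper-parameters that are estimator-specific; a `test = "shrunken"` mode
  (per-miRNA variance shrunk toward the across-miRNA mean with weight
  `shrink_weight`) is provided for sensitivity analysis. Fold-change
  arithmetic is exact either way; p-values differ across t variants, which
  is why the package's published-table check targets the fold-change column
  and not the p column.
* **Degenerate variance at n = 2 per group** is reachable: zero pooled
  variance with zero difference returns \(p = 1\); zero variance with a
  nonzero difference returns \(p = 0\) with a warning.
* **Target genes missing from the pathway universe** still count toward the
  target-set size in ORA — silently shrinking \(n\) would inflate
  significance.
* **MCL inflation** controls granularity and the value used by plugin-based
  analyses is generally unrecorded; the default 2.0 is the algorithm's
  canonical setting, and the package's correctness checks use structures
  (disconnected components, cliques joined by a weak bridge) whose clustering
  is insensitive to inflation in a wide band.

## What the synthetic generator emulates

`simulate_study()` produces every pipeline input with planted ground truth:

* **Expression** — a 2006-miRNA array, 2 biological replicates per group.
  Each miRNA's baseline log2 intensity is drawn from
  \(\mathcal N(7,\,2^2)\) (log-normal on the natural scale: positive,
  right-skewed, median ≈ 128, in the realistic range for summarized
  single-channel array signals), planted responsive miRNAs are shifted by
  \(\pm\) `planted_log2fc`/2 per group, and i.i.d. replicate noise of sd 0.25
  log2 units is added — a typical between-biological-replicate spread for
  cell-line array experiments, and the value that determines the power of
  the planted-effect recovery checks. All randomness flows through
  deterministic sub-streams of one seed, so identical configs give
  byte-identical files.
* **Pathways** — 400 gene sets of 20–200 genes over a 28000-gene universe.
  The first `n_blocks * pathways_per_block` pathways are reserved for the
  planted blocks: members of block *b* receive 5 target genes from each of
  their block's 8 pathways plus 60 background targets, so block members are
  mutually enriched in the same pathways and the network recovers the blocks
  as clusters.
* **Predictions** — source A rank-scored with truth targets at the strongest
  ranks; source B \([0,1]\)-scored with each truth target passing the 0.7
  cut-off with probability `source_agreement` (Beta-shaped scores on either
  side of the cut). At agreement 1 the consensus returns the truth sets
  exactly; at agreement \(a\) it is a Binomial(\(|T|, a\)) thinning.

What it deliberately does **not** model: probe-level replication (~30
probes/miRNA), spike-ins, dye or batch effects, correlated noise across
miRNAs, and any sequence-level realism in target prediction. Passing the
planted-recovery checks therefore demonstrates that the pipeline's inference
machinery is correct under its own assumptions — not that those assumptions
capture every property of a real array experiment.

## Numerical choices

* Hypergeometric tails are evaluated through the survival function of R's
  `phyper` (log-gamma based), never by naive summation; the test suite pins
  them against exact combinatorial enumeration over the entire small-parameter
  grid (all universes up to 25; ~38,000 cases; agreement within 1e-12).
* Quantile normalization uses mean-of-tied-reference-ranks tie handling and
  is idempotent.
* MCL prunes entries below 1e-5 after inflation and declares convergence when
  the largest entry change drops below 1e-6; a column emptied by pruning gets
  its self-flow restored. Non-convergence at 100 iterations returns the
  current partition with a warning.
* Verification problem sizes: planted-effect recovery is averaged over 20
  seeds at 500 miRNAs / 50 planted; block recovery over 10 seeds of the full
  pipeline at 300 miRNAs with two 10-member blocks; MCL is compared with an
  independently written dense reference on 50 random 30-node weighted graphs.
  These sizes give stable averages (binomial/ARI standard errors well inside
  the margins checked) while keeping the whole suite fast enough to run on
  every change.

## Known limitations

* The pair-overlap test treats each miRNA's pathway set as a uniform draw
  from the collection; popular pathways (large, frequently enriched) violate
  this and make small p-values easier to reach. The fixed-\(N\) convention
  inherits this bias knowingly, since the resulting ranking — not the
  calibrated error rate — is what the downstream degree and cluster analyses
  consume.
* With two replicates per group the t-test has two degrees of freedom;
  power comes almost entirely from effect size, and p-values near the 0.05
  boundary are fragile. The shrunken-variance mode trades calibration for
  stability.
* Gene-mode networks (linking miRNAs by shared consensus targets with
  \(N = 28000\)) are supported by the same machinery (`mode = "gene"`), but
  edge weights are then target counts, and the 2.9 weight threshold tuned to
  pathway counts is unlikely to be meaningful there.
* MCL on overlapping attractor systems resolves ties deterministically but
  arbitrarily; partitions are reproducible, not unique.

## A minimal run

```{r example}
cfg <- sim_config(n_mirnas = 300, n_responsive = 30, n_blocks = 2,
                  block_size = 10, seed = 42)
st <- simulate_study(cfg)
fit <- mirnet(st$matrix, st$design, st$pred_a, st$pred_b, st$db)
fit
head(fit$centrality)
lengths(fit$clustering$clusters)
```

The two planted blocks surface as the two clusters; the block members'
degrees dominate the centrality table because each block member shares its
eight planted pathways with every other member of its block.
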