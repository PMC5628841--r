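#' Quantile-normalize a positive signal matrix
#'
#' Forces every array (column) onto a common intensity distribution: each
#' column's sorted values are replaced by the across-column mean of the values
#' at the same rank. Tied values within a column receive the mean of the
#' reference values at their tied ranks. Row and column names are preserved.
#'
#' @param mat numeric matrix of strictly positive intensities, rows = miRNAs,
#'   columns = samples.
#' @return matrix of the same dimensions and dimnames.
#' @examples
#' m <- cbind(a = c(2, 6), b = c(4, 8))
#' quantile_normalize(m) # both columns become (3, 7)
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("intensity matrix must be numeric")
  if (anyNA(mat)) stop("intensity matrix contains missing values")
  if (any(mat <= 0)) stop("intensity matrix must be strictly positive")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Geometric mean of positive intensities
#'
#' @param x numeric vector, all values > 0.
#' @return `exp(mean(log(x)))`.
#' @examples
#' geometric_mean(c(4, 9)) # 6
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("geometric mean of an empty vector is undefined")
  if (anyNA(x) || any(x <= 0)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

#' Signed fold change between two geometric means
#'
#' The ratio treated/control when it is at least 1, otherwise the negated
#' reciprocal, so magnitude is always >= 1 and sign encodes direction
#' (positive = up in the treated group).
#'
#' @param gmean_treated,gmean_control positive geometric mean intensities.
#' @return signed fold change (vectorised).
#' @examples
#' signed_fold_change(76.9, 10)       #  7.69
#' signed_fold_change(33.72, 299.95)  # -8.895...
#' @export
signed_fold_change <- function(gmean_treated, gmean_control) {
  if (anyNA(gmean_treated) || anyNA(gmean_control) ||
      any(gmean_treated <= 0) || any(gmean_control <= 0)) {
    stop("fold change requires positive geometric means")
  }
  r <- gmean_treated / gmean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Two-sample test on log2 intensities
#'
#' Two-sided p-value from a two-sample t statistic on log2-transformed
#' intensities. `"student"` pools the variance, `"welch"` uses the
#' Satterthwaite approximation, `"shrunken"` pools each feature's variance
#' toward a common variance estimate with weight `shrink_weight` (a light
#' stand-in for moderated-variance tests when only the common variance is
#' available; see Details).
#'
#' Degenerate case (reachable at n = 2 per group on near-constant features):
#' zero pooled variance with zero mean difference returns p = 1; zero variance
#' with a nonzero difference returns p = 0 with a warning.
#'
#' @param group_a,group_b numeric vectors of positive intensities (>= 2 each).
#' @param test one of `"student"`, `"welch"`, `"shrunken"`.
#' @param shrink_weight weight in \[0,1\] given to the common variance under
#'   `test = "shrunken"`; `common_s2` supplies that common variance (defaults
#'   to the pooled variance of the feature itself, i.e. no effect, so callers
#'   testing many features pass the across-feature mean variance).
#' @param common_s2 optional common variance on the log2 scale.
#' @return two-sided p-value.
#' @export
two_sample_test <- function(group_a, group_b, test = c("student", "welch", "shrunken"),
                            shrink_weight = 0.5, common_s2 = NULL) {
  test <- match.arg(test)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (any(c(group_a, group_b) <= 0)) stop("intensities must be positive")
  a <- log2(group_a); b <- log2(group_b)
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (test == "welch") {
    se2 <- va / na + vb / nb
    if (se2 == 0) return(degenerate_p(d))
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tt <- d / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (test == "shrunken") {
      if (is.null(common_s2)) common_s2 <- sp2
      sp2 <- (1 - shrink_weight) * sp2 + shrink_weight * common_s2
    }
    if (sp2 == 0) return(degenerate_p(d))
    df <- na + nb - 2
    tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
  }
  2 * stats::pt(-abs(tt), df)
}

degenerate_p <- function(d) {
  if (d == 0) return(1)
  warning("zero variance with nonzero group difference; returning p = 0")
  0
}

#' Differential expression table for a two-group design
#'
#' Quantile-normalizes the matrix (optional), then per miRNA computes the
#' geometric mean of each group on the normalized unlogged scale, the signed
#' fold change, and a two-sample test p-value on log2 intensities.
#'
#' @param mat positive intensity matrix, rows = miRNAs, columns = samples.
#' @param design data.frame with columns `sample_id` and `group`; `group`
#'   must take exactly the two values named by `treated` and `control`.
#' @param treated,control group labels.
#' @param normalize quantile-normalize before testing (default TRUE).
#' @param test passed to [two_sample_test()]; under `"shrunken"` the common
#'   variance is the across-miRNA mean of pooled log2 variances.
#' @param shrink_weight see [two_sample_test()].
#' @return data.frame with columns `mirna_id`, `gmean_treated`,
#'   `gmean_control`, `fold_change`, `p_value`, `direction` ("up"/"down").
#' @export
differential_expression <- function(mat, design, treated = "treated",
                                    control = "control", normalize = TRUE,
                                    test = "student", shrink_weight = 0.5) {
  mat <- as.matrix(mat)
  check_design(mat, design, treated, control)
  if (normalize) mat <- quantile_normalize(mat)
  idx_t <- design$sample_id[design$group == treated]
  idx_c <- design$sample_id[design$group == control]
  mt <- mat[, idx_t, drop = FALSE]
  mc <- mat[, idx_c, drop = FALSE]
  gm_t <- apply(mt, 1L, geometric_mean)
  gm_c <- apply(mc, 1L, geometric_mean)
  fc <- signed_fold_change(gm_t, gm_c)
  common_s2 <- NULL
  if (identical(test, "shrunken")) {
    vt <- apply(log2(mt), 1L, stats::var)
    vc <- apply(log2(mc), 1L, stats::var)
    sp2 <- ((ncol(mt) - 1) * vt + (ncol(mc) - 1) * vc) / (ncol(mt) + ncol(mc) - 2)
    common_s2 <- mean(sp2)
  }
  p <- vapply(seq_len(nrow(mat)), function(i) {
    suppressWarnings(two_sample_test(mt[i, ], mc[i, ], test = test,
                                     shrink_weight = shrink_weight,
                                     common_s2 = common_s2))
  }, numeric(1))
  data.frame(
    mirna_id = rownames(mat),
    gmean_treated = unname(gm_t),
    gmean_control = unname(gm_c),
    fold_change = unname(fc),
    p_value = p,
    direction = ifelse(fc > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

check_design <- function(mat, design, treated, control) {
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design needs columns 'sample_id' and 'group'")
  }
  if (is.null(colnames(mat)) || is.null(rownames(mat))) {
    stop("intensity matrix needs row (miRNA) and column (sample) names")
  }
  if (!setequal(design$sample_id, colnames(mat))) {
    stop("design sample ids do not match matrix columns")
  }
  groups <- unique(design$group)
  if (!setequal(groups, c(treated, control))) {
    stop(sprintf("design groups must be exactly {%s, %s}", treated, control))
  }
  n_t <- sum(design$group == treated); n_c <- sum(design$group == control)
  if (n_t < 2L || n_c < 2L) stop("each group needs at least 2 samples")
  invisible(TRUE)
}

#' Call responsive miRNAs
#'
#' Keeps records passing both cut-offs: p-value strictly below `p_cut` and
#' absolute fold change strictly above `fc_cut`.
#'
#' @param records data.frame from [differential_expression()].
#' @param p_cut p-value cut-off (default 0.05).
#' @param fc_cut fold-change magnitude cut-off (default 2).
#' @return the responsive subset, with `direction` retained.
#' @export
call_responsive <- function(records, p_cut = 0.05, fc_cut = 2) {
  needed <- c("mirna_id", "fold_change", "p_value", "direction")
  if (!all(needed %in% names(records))) {
    stop("records must carry mirna_id, fold_change, p_value, direction")
  }
  keep <- records$p_value < p_cut & abs(records$fold_change) > fc_cut
  records[keep, , drop = FALSE]
}
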