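#' Drop miRNAs with too many undetected samples
#'
#' Keeps the miRNAs detected in at least `min_fraction` of samples (the
#' conventional rule drops a miRNA undetected in more than 30% of samples,
#' i.e. `min_fraction = 0.7`). Remaining undetected cells are imputed with
#' the row mean of the detected values, which perturbs per-row variance less
#' than any fixed fill value.
#'
#' @param expr An [expr_mat()].
#' @param min_fraction Minimum detected fraction in (0, 1]; default 0.7.
#' @return An [expr_mat()] with only the kept rows, fully imputed (all-true
#'   detection mask is preserved as the record of originally detected cells).
#' @export
detection_filter <- function(expr, min_fraction = 0.7) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(expr$detection)
  keep <- frac >= min_fraction
  vals <- expr$values[keep, , drop = FALSE]
  det <- expr$detection[keep, , drop = FALSE]
  for (i in which(!apply(det, 1, all))) {
    vals[i, !det[i, ]] <- mean(vals[i, det[i, ]])
  }
  expr_mat(vals, detection = det & TRUE) # mask retained; values imputed
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch test: `t = (mean0 - mean1) / sqrt(s0^2/n0 + s1^2/n1)`
#' with Welch-Satterthwaite degrees of freedom. Two degenerate inputs are
#' defined by convention rather than erroring: two constant equal groups give
#' `t = 0, p = 1`; two constant unequal groups give `p = 0`.
#'
#' @param group0,group1 Numeric vectors, each of length >= 2.
#' @return A named list `list(t = , p = , df = )`.
#' @examples
#' welch_test(c(10, 12, 14, 16), c(1, 2, 3))
#' @export
welch_test <- function(group0, group1) {
  n0 <- length(group0); n1 <- length(group1)
  if (n0 < 2 || n1 < 2) stop("each group needs >= 2 values", call. = FALSE)
  v0 <- stats::var(group0); v1 <- stats::var(group1)
  se2 <- v0 / n0 + v1 / n1
  if (se2 == 0) {
    if (mean(group0) == mean(group1)) return(list(t = 0, p = 1, df = n0 + n1 - 2))
    return(list(t = sign(mean(group0) - mean(group1)) * Inf, p = 0,
                df = n0 + n1 - 2))
  }
  tval <- (mean(group0) - mean(group1)) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Pre-screen miRNAs by Welch's t-test
#'
#' Runs [welch_test()] on every row of `expr`, splitting samples by class,
#' and keeps rows with `p <= alpha` (a row at exactly `p = alpha` survives;
#' the filter removes p-values *greater than* the cutoff). P-values are not
#' adjusted for multiple testing unless `bh = TRUE`, in which case the
#' Benjamini-Hochberg adjusted values are filtered instead.
#'
#' @param expr An [expr_mat()], already detection-filtered.
#' @param labels Sample labels from [sample_labels()] / [read_labels()].
#' @param alpha P-value cutoff in (0, 1); default 0.05.
#' @param bh Apply Benjamini-Hochberg adjustment before filtering? Default
#'   `FALSE`, matching the plain per-miRNA screen.
#' @return A tibble with one row per input miRNA: `mirna_id`, `t`, `p`
#'   (and `p_adj` when `bh = TRUE`), `kept`, and `status` in
#'   `{"kept", "not_significant"}`, in the input row order.
#' @export
ttest_screen <- function(expr, labels, alpha = 0.05, bh = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  cls <- align_classes(labels, expr)
  g0 <- expr$values[, cls == levels(cls)[1], drop = FALSE]
  g1 <- expr$values[, cls == levels(cls)[2], drop = FALSE]
  res <- lapply(seq_len(nrow(g0)), function(i) welch_test(g0[i, ], g1[i, ]))
  out <- tibble::tibble(
    mirna_id = mirna_ids(expr),
    t = vapply(res, `[[`, numeric(1), "t"),
    p = vapply(res, `[[`, numeric(1), "p")
  )
  p_screen <- out$p
  if (bh) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    p_screen <- out$p_adj
  }
  out$kept <- p_screen <= alpha
  out$status <- ifelse(out$kept, "kept", "not_significant")
  if (!any(out$kept)) {
    stop("no miRNA passed the t-test screen; nothing to cluster", call. = FALSE)
  }
  out
}

#' Signal-to-noise ratio of a two-group split
#'
#' `(mean0 - mean1) / (sd0 + sd1)` with sample standard deviations. When both
#' groups are constant the score is 0 for equal means and `Inf` (a rank-first
#' sentinel) for unequal means.
#'
#' @param group0,group1 Numeric vectors, each of length >= 2.
#' @return A single number; swap the groups and it changes sign.
#' @export
snr_score <- function(group0, group1) {
  denom <- stats::sd(group0) + stats::sd(group1)
  num <- mean(group0) - mean(group1)
  if (denom == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / denom
}
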