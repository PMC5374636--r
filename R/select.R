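#' Choose one representative miRNA per cluster
#'
#' Four criteria are available; all ties are broken lexicographically by
#' miRNA id so selection is deterministic and permutation-invariant:
#'
#' * `"fda"` — the member with the largest absolute Fisher-discriminant
#'   weight. With `w_mode = "global"` (default) one discriminant is fitted
#'   over all clustered miRNAs and each cluster reads its members' weights
#'   off that vector; with `w_mode = "cluster"` a separate discriminant is
#'   fitted per cluster (numerically steadier when miRNAs far outnumber
#'   samples). If the weight vector vanishes on a cluster, that cluster
#'   falls back to the center criterion with a warning.
#' * `"ttest"` — the member with the smallest Welch p-value.
#' * `"snr"` — the member with the largest absolute signal-to-noise ratio
#'   ([snr_score()]).
#' * `"center"` — the member closest (by `metric`) to the mean expression
#'   profile of the cluster.
#'
#' @param clusters A `cluster_set`.
#' @param expr An [expr_mat()] containing every clustered miRNA.
#' @param labels Sample labels.
#' @param criterion One of `"fda"`, `"ttest"`, `"snr"`, `"center"`.
#' @param w_mode `"global"` or `"cluster"` (FDA criterion only).
#' @param metric Distance for the center criterion: `"correlation"` or
#'   `"euclidean"`; use the metric the clustering used.
#' @param screen Optional screen tibble from [ttest_screen()]; recomputed
#'   when absent (t-test criterion only).
#' @param ridge Passed to [fit_fda()].
#' @return A tibble with one row per cluster: `cluster_id`, `criterion`,
#'   `representative_id`, `score` (the criterion value achieved, on the
#'   scale the criterion optimises).
#' @export
select_representatives <- function(clusters, expr, labels,
                                   criterion = c("fda", "ttest", "snr", "center"),
                                   w_mode = c("global", "cluster"),
                                   metric = c("correlation", "euclidean"),
                                   screen = NULL, ridge = FALSE) {
  criterion <- match.arg(criterion)
  w_mode <- match.arg(w_mode)
  metric <- match.arg(metric)
  members <- clusters$members
  all_ids <- unlist(members)

  pick <- function(ids, scores, maximize = TRUE) {
    # lexicographic tie-break on id; scores compared at 10 significant digits
    # so exact duplicates tie even after floating-point linear algebra
    s <- signif(if (maximize) scores else -scores, 10)
    ord <- order(-s, ids)
    list(id = ids[ord[1]], score = scores[ord[1]])
  }

  rows <- switch(criterion,
    fda = {
      gw <- NULL
      if (w_mode == "global") {
        gw <- cluster_fda(expr, labels, all_ids, ridge = ridge)$w
        names(gw) <- all_ids
      }
      lapply(members, function(ids) {
        if (w_mode == "global") {
          wts <- abs(gw[ids])
        } else if (length(ids) == 1) {
          wts <- stats::setNames(1, ids)
        } else {
          wts <- abs(stats::setNames(cluster_fda(expr, labels, ids,
                                                 ridge = ridge)$w, ids))
        }
        if (all(wts == 0)) {
          warning("discriminant weight vanishes on a cluster; using center criterion")
          return(center_pick(ids, expr, metric))
        }
        pick(ids, wts)
      })
    },
    ttest = {
      if (is.null(screen)) screen <- ttest_screen(expr, labels, alpha = 1 - 1e-12)
      pv <- stats::setNames(screen$p, screen$mirna_id)
      lapply(members, function(ids) pick(ids, pv[ids], maximize = FALSE))
    },
    snr = {
      cls <- align_classes(labels, expr)
      i0 <- cls == levels(cls)[1]
      lapply(members, function(ids) {
        sub <- expr_subset(expr, ids)$values
        s <- abs(vapply(seq_along(ids), function(j) {
          snr_score(sub[j, i0], sub[j, !i0])
        }, numeric(1)))
        pick(ids, stats::setNames(s, ids))
      })
    },
    center = lapply(members, function(ids) center_pick(ids, expr, metric))
  )

  tibble::tibble(
    cluster_id = seq_along(members),
    criterion = criterion,
    representative_id = vapply(rows, `[[`, character(1), "id"),
    score = vapply(rows, function(r) as.numeric(r$score), numeric(1))
  )
}

# Internal: member nearest the cluster's mean profile
center_pick <- function(ids, expr, metric) {
  sub <- expr_subset(expr, ids)$values
  if (length(ids) == 1) return(list(id = ids, score = 0))
  ctr <- colMeans(sub)
  d <- vapply(seq_along(ids), function(j) {
    if (metric == "euclidean") return(sqrt(sum((sub[j, ] - ctr)^2)))
    if (stats::sd(sub[j, ]) == 0 || stats::sd(ctr) == 0) return(2)
    1 - stats::cor(sub[j, ], ctr)
  }, numeric(1))
  ord <- order(d, ids)
  list(id = ids[ord[1]], score = d[ord[1]])
}
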