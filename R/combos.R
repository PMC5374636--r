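# Run expr with a private RNG stream, leaving the caller's stream untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Stratified cross-validation fold assignment
#'
#' Samples are shuffled within each class under the given seed and dealt
#' round-robin into folds, so every fold contains both classes whenever each
#' class has at least `folds` samples. If the smaller class has fewer
#' samples than `folds`, the number of folds is reduced to that size with a
#' warning. The assignment depends only on `(classes, folds, seed)`, never
#' on which features are being scored, so every combination — and the
#' exhaustive oracle — is evaluated on identical folds.
#'
#' @param classes Two-level factor of sample classes.
#' @param folds Number of folds; default 5.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..folds) aligned to `classes`.
#' @export
cv_folds <- function(classes, folds = 5, seed = 1) {
  classes <- as.factor(classes)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  smallest <- min(table(classes))
  if (smallest < folds) {
    warning(sprintf("smallest class has %d samples; reducing folds from %d to %d",
                    smallest, folds, smallest))
    folds <- smallest
  }
  assign_out <- integer(length(classes))
  with_local_seed(seed, {
    for (lv in levels(classes)) {
      idx <- which(classes == lv)
      idx <- idx[sample.int(length(idx))]
      assign_out[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_out
}

#' Enumerate k-combinations of representative miRNAs
#'
#' @param rep_ids Character vector of miRNA ids.
#' @param k Combination size, `1 <= k <= length(rep_ids)`.
#' @param budget Refuse to enumerate more than this many combinations
#'   (default 2e6) — lower `k` or tighten the clustering instead.
#' @return Character matrix with `k` rows, one column per combination,
#'   members sorted within a combination and columns in lexicographic order.
#' @export
enumerate_combos <- function(rep_ids, k, budget = 2e6) {
  n <- length(rep_ids)
  if (k < 1 || k > n) stop("k must lie in 1..length(rep_ids)", call. = FALSE)
  n_combos <- choose(n, k)
  if (n_combos > budget) {
    stop(sprintf(
      "C(%d, %d) = %.0f combinations exceeds the budget of %.0f; lower k or tighten clustering",
      n, k, n_combos, budget), call. = FALSE)
  }
  utils::combn(sort(rep_ids), k)
}

#' Score one miRNA combination by cross-validated SVM accuracy
#'
#' The samples, restricted to the member miRNAs as features, are classified
#' with a radial-basis-kernel support vector machine at library defaults
#' (cost 1, kernel width 1/k) under stratified cross-validation. Confusion
#' counts are pooled over the folds (micro-average), then sensitivity
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)` and total accuracy `(TP+TN)/n`
#' are computed with class c0 — the first label level — as positive.
#'
#' @param expr An [expr_mat()].
#' @param labels Sample labels.
#' @param members miRNA ids of the combination.
#' @param folds Number of CV folds; default 5.
#' @param seed Integer seed for the fold assignment.
#' @param fold_id Optional precomputed assignment from [cv_folds()]
#'   (overrides `folds`/`seed`); used to share folds across many calls.
#' @return A one-row tibble: `members` (ids joined by `";"`), `k`,
#'   `sensitivity`, `specificity`, `total_accuracy`, `fold_accuracies`
#'   (list column).
#' @export
score_combo <- function(expr, labels, members, folds = 5, seed = 1,
                        fold_id = NULL) {
  cls <- align_classes(labels, expr)
  if (is.null(fold_id)) fold_id <- cv_folds(cls, folds, seed)
  x <- t(expr_subset(expr, members)$values) # samples x k
  colnames(x) <- members
  pos <- levels(cls)[1]
  tp <- fp <- tn <- fn <- 0
  fold_acc <- numeric(0)
  scale_cols <- apply(x, 2, stats::sd) > 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    fit <- e1071::svm(x[!test, , drop = FALSE], cls[!test],
                      kernel = "radial", scale = scale_cols)
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    truth <- cls[test]
    tp <- tp + sum(pred == pos & truth == pos)
    fn <- fn + sum(pred != pos & truth == pos)
    tn <- tn + sum(pred != pos & truth != pos)
    fp <- fp + sum(pred == pos & truth != pos)
    fold_acc <- c(fold_acc, mean(pred == truth))
  }
  k <- length(members)
  tibble::tibble(
    members = paste(sort(members), collapse = ";"),
    k = k,
    sensitivity = tp / (tp + fn),
    specificity = tn / (fp + tn),
    total_accuracy = (tp + tn) / length(cls),
    fold_accuracies = list(fold_acc)
  )
}

#' Rank all k-combinations of a representative set
#'
#' Enumerates every combination of size 1..`k_max` of `rep_ids`, scores each
#' with [score_combo()] on one shared fold assignment, and ranks the
#' combinations of each size by total accuracy (descending), breaking ties
#' lexicographically on the sorted member ids. Given the same seed the
#' ranking is fully deterministic.
#'
#' @param expr An [expr_mat()].
#' @param labels Sample labels.
#' @param rep_ids Representative miRNA ids to combine.
#' @param k_max Largest combination size; default 4 (capped at
#'   `length(rep_ids)`).
#' @param folds,seed,budget See [score_combo()] and [enumerate_combos()].
#' @return A `combo_ranking` tibble: `k`, `rank` (1..C(n,k) within each k),
#'   `members`, `sensitivity`, `specificity`, `total_accuracy`,
#'   `fold_accuracies`.
#' @export
rank_combos <- function(expr, labels, rep_ids, k_max = 4, folds = 5, seed = 1,
                        budget = 2e6) {
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  k_max <- min(k_max, length(rep_ids))
  cls <- align_classes(labels, expr)
  fold_id <- cv_folds(cls, folds, seed)
  out <- dplyr::bind_rows(lapply(seq_len(k_max), function(k) {
    combos <- enumerate_combos(rep_ids, k, budget)
    scored <- dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(j) {
      score_combo(expr, labels, combos[, j], fold_id = fold_id)
    }))
    scored <- scored[order(-scored$total_accuracy, scored$members), ]
    scored$rank <- seq_len(nrow(scored))
    scored
  }))
  out <- out[, c("k", "rank", "members", "sensitivity", "specificity",
                 "total_accuracy", "fold_accuracies")]
  attr(out, "classifier_spec") <- "radial-basis SVM, cost 1, gamma 1/k, stratified CV"
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("combo_ranking", class(out))
  out
}

#' @export
print.combo_ranking <- function(x, ...) {
  cat(sprintf("<combo_ranking> %d combinations, k in %s (seed %s)\n",
              nrow(x), paste(range(x$k), collapse = ".."),
              format(attr(x, "seed"))))
  NextMethod()
}

#' One-row summary of a combination ranking
#'
#' @param x A `combo_ranking`.
#' @param ... Unused.
#' @return A one-row tibble: number of combinations, largest k, and the best
#'   combination with its accuracy measures.
#' @export
glance.combo_ranking <- function(x, ...) {
  best <- x[which.max(x$total_accuracy), ]
  tibble::tibble(
    n_combos = nrow(x), k_max = max(x$k),
    best_members = best$members,
    best_total_accuracy = best$total_accuracy,
    best_sensitivity = best$sensitivity,
    best_specificity = best$specificity
  )
}
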