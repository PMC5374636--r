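#' Exhaustive-search oracle ranking
#'
#' Scores every k-combination of the kept miRNAs — not just the cluster
#' representatives — with the identical fold assignment and tie rule as
#' [rank_combos()], giving the "true rank" of each combination. Feasible
#' only at modest scale; guarded by the same combination budget.
#'
#' @param expr An [expr_mat()].
#' @param labels Sample labels.
#' @param kept_ids All candidate miRNA ids (the post-screen universe).
#' @param k Combination size.
#' @param folds,seed,budget See [rank_combos()].
#' @return A `combo_ranking` tibble for the single size `k`, whose `rank`
#'   column is a bijection onto `1..C(length(kept_ids), k)`.
#' @export
exhaustive_oracle <- function(expr, labels, kept_ids, k, folds = 5, seed = 1,
                              budget = 2e6) {
  out <- rank_combos(expr, labels, kept_ids, k_max = k, folds = folds,
                     seed = seed, budget = budget)
  out[out$k == k, ]
}

#' Average true rank of a search's top combinations
#'
#' The mean, over the `n` best combinations found by a (representative-based)
#' search, of each combination's rank in the exhaustive-search oracle. The
#' floor is `(n+1)/2`, attained exactly when the search's top n are the true
#' top n.
#'
#' @param searched A `combo_ranking` (or tibble with `members` and `rank`)
#'   from the search, one combination size.
#' @param oracle The [exhaustive_oracle()] ranking for the same size.
#' @param n How many top search results to evaluate; must not exceed the
#'   searched list.
#' @return A single number `>= (n+1)/2`.
#' @export
avg_rank <- function(searched, oracle, n) {
  top <- true_ranks(searched, oracle, n)
  mean(top)
}

#' Hit ratio of a search's top combinations
#'
#' The fraction of the search's `n` best combinations whose oracle rank is
#' at most `n` (i.e. that truly belong to the top n).
#'
#' @inheritParams avg_rank
#' @return A number in `[0, 1]`.
#' @export
hit_ratio <- function(searched, oracle, n) {
  top <- true_ranks(searched, oracle, n)
  mean(top <= n)
}

# Internal: oracle ranks of the search's top-n combos
true_ranks <- function(searched, oracle, n) {
  searched <- searched[order(searched$rank), ]
  if (n < 1 || n > nrow(searched)) {
    stop("n must lie in 1..number of searched combinations", call. = FALSE)
  }
  keys <- searched$members[seq_len(n)]
  idx <- match(keys, oracle$members)
  if (anyNA(idx)) {
    stop("searched combination absent from the oracle ranking: ",
         paste(keys[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  oracle$rank[idx]
}

#' Compare representative-selection criteria against the oracle
#'
#' For each selection criterion, picks representatives, ranks all their
#' k-combinations, and measures search quality ([avg_rank()], [hit_ratio()])
#' against the exhaustive oracle over all kept miRNAs, at each list length
#' in `n_list` (capped at the number of searched combinations, with a
#' warning). All criteria and the oracle share one fold assignment.
#'
#' @param expr An [expr_mat()] restricted to the kept miRNAs.
#' @param labels Sample labels.
#' @param clusters A `cluster_set` over the kept miRNAs.
#' @param k_max Largest combination size; default 2.
#' @param n_list Top-list lengths to evaluate; default `c(10, 100)`.
#' @param folds,seed,budget See [rank_combos()].
#' @param criteria Which criteria to compare; default all four.
#' @param w_mode,metric,screen Passed to [select_representatives()].
#' @return A tibble: `criterion`, `k`, `n`, `avg_rank`, `hit_ratio`,
#'   `n_searched`.
#' @export
compare_criteria <- function(expr, labels, clusters, k_max = 2,
                             n_list = c(10, 100), folds = 5, seed = 1,
                             budget = 2e6,
                             criteria = c("fda", "ttest", "snr", "center"),
                             w_mode = "global", metric = "correlation",
                             screen = NULL) {
  kept_ids <- unlist(clusters$members)
  k_max <- min(k_max, length(clusters))
  oracles <- lapply(seq_len(k_max), function(k) {
    exhaustive_oracle(expr, labels, kept_ids, k, folds = folds, seed = seed,
                      budget = budget)
  })
  dplyr::bind_rows(lapply(criteria, function(cr) {
    reps <- select_representatives(clusters, expr, labels, criterion = cr,
                                   w_mode = w_mode, metric = metric,
                                   screen = screen)
    ranking <- rank_combos(expr, labels, reps$representative_id, k_max = k_max,
                           folds = folds, seed = seed, budget = budget)
    dplyr::bind_rows(lapply(seq_len(k_max), function(k) {
      searched <- ranking[ranking$k == k, ]
      dplyr::bind_rows(lapply(n_list, function(n) {
        n_eff <- min(n, nrow(searched))
        if (n_eff < n) {
          warning(sprintf("n = %d capped at the %d searched combinations (k = %d)",
                          n, n_eff, k))
        }
        tibble::tibble(
          criterion = cr, k = k, n = n_eff,
          avg_rank = avg_rank(searched, oracles[[k]], n_eff),
          hit_ratio = hit_ratio(searched, oracles[[k]], n_eff),
          n_searched = nrow(searched)
        )
      }))
    }))
  }))
}
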