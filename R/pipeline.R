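#' Run the full combinatorial-biomarker search
#'
#' Chains the whole procedure: detection filter, Welch t-test screen,
#' average-linkage clustering cut by the inconsistency coefficient,
#' projection-loss cluster refinement, representative selection, and
#' cross-validated ranking of all k-combinations of the representatives.
#'
#' @param expr An [expr_mat()] (or a data frame in the layout of
#'   [as_expr_mat()]).
#' @param labels Sample labels ([sample_labels()] / [read_labels()]).
#' @param alpha Welch screen p-value cutoff; default 0.05.
#' @param detection_fraction Minimum detected fraction; default 0.7.
#' @param distance_metric `"correlation"` (default) or `"euclidean"`.
#' @param inconsistency_threshold Dendrogram cut threshold; default 1.
#' @param msl_threshold `MSL'` split threshold; default 0.65.
#' @param k_max Largest combination size (<= 6); default 4.
#' @param cv_folds Cross-validation folds; default 5.
#' @param selection_criterion `"fda"` (default), `"ttest"`, `"snr"` or
#'   `"center"`.
#' @param w_mode `"global"` or `"cluster"` for the FDA criterion.
#' @param refine Apply the `MSL'`/MLR refinement? Default `TRUE`.
#' @param bh Benjamini-Hochberg adjust the screen p-values? Default `FALSE`.
#' @param seed Integer seed driving every random choice (CV folds).
#' @param budget Combination budget; see [enumerate_combos()].
#' @return A `mircombo_run` list: `config`, `counts`, `screen` (tibble),
#'   `clusters` (`cluster_set` with diagnostics), `representatives`
#'   (tibble), `ranking` (`combo_ranking`).
#' @examples
#' \donttest{
#' sim <- generate_synthetic(synth_spec(n_clusters = 4, cluster_sizes = 4,
#'                                      n0 = 20, n1 = 20, seed = 7))
#' run <- run_pipeline(sim$expr, sim$labels, k_max = 2, seed = 7)
#' glance(run)
#' }
#' @export
run_pipeline <- function(expr, labels,
                         alpha = 0.05, detection_fraction = 0.7,
                         distance_metric = c("correlation", "euclidean"),
                         inconsistency_threshold = 1, msl_threshold = 0.65,
                         k_max = 4, cv_folds = 5,
                         selection_criterion = c("fda", "ttest", "snr", "center"),
                         w_mode = c("global", "cluster"),
                         refine = TRUE, bh = FALSE, seed = 1, budget = 2e6) {
  if (is.data.frame(expr)) expr <- as_expr_mat(expr)
  distance_metric <- match.arg(distance_metric)
  selection_criterion <- match.arg(selection_criterion)
  w_mode <- match.arg(w_mode)
  if (k_max < 1 || k_max > 6) stop("k_max must lie in 1..6", call. = FALSE)
  config <- list(
    alpha = alpha, detection_fraction = detection_fraction,
    distance_metric = distance_metric,
    inconsistency_threshold = inconsistency_threshold,
    msl_threshold = msl_threshold, k_max = k_max, cv_folds = cv_folds,
    selection_criterion = selection_criterion, w_mode = w_mode,
    refine = refine, bh = bh, seed = seed,
    positive_class = levels(labels$class)[1]
  )

  p_initial <- nrow(expr$values)
  expr_det <- detection_filter(expr, detection_fraction)
  screen <- ttest_screen(expr_det, labels, alpha = alpha, bh = bh)
  kept <- screen$mirna_id[screen$kept]
  expr_kept <- expr_subset(expr_det, kept)

  if (length(kept) < 2) {
    raw <- trivial_clusters(kept)
    clusters <- raw
  } else {
    dend <- average_linkage(expr_dist(expr_kept, distance_metric))
    raw <- cut_by_inconsistency(dend, inconsistency_threshold)
    clusters <- if (refine) {
      refine_clusters(raw, expr_kept, labels, msl_threshold)
    } else raw
  }

  reps <- select_representatives(clusters, expr_kept, labels,
                                 criterion = selection_criterion,
                                 w_mode = w_mode, metric = distance_metric,
                                 screen = screen)
  ranking <- rank_combos(expr_kept, labels, reps$representative_id,
                         k_max = k_max, folds = cv_folds, seed = seed,
                         budget = budget)
  structure(list(
    config = config,
    counts = list(
      p_initial = p_initial,
      p_after_detection = nrow(expr_det$values),
      p_after_ttest = length(kept),
      n_raw_clusters = length(raw),
      n_final_clusters = length(clusters),
      n_representatives = nrow(reps),
      n_combos = nrow(ranking)
    ),
    screen = screen, clusters = clusters, representatives = reps,
    ranking = ranking
  ), class = "mircombo_run")
}

#' @export
print.mircombo_run <- function(x, ...) {
  with(x$counts, cat(sprintf(
    paste0("<mircombo_run> %d miRNAs -> %d detected -> %d significant -> ",
           "%d clusters -> %d representatives; %d combinations ranked\n"),
    p_initial, p_after_detection, p_after_ttest, n_final_clusters,
    n_representatives, n_combos)))
  best <- glance(x)
  cat(sprintf("  best combination: %s (TA %.3f)\n",
              best$best_members, best$best_total_accuracy))
  invisible(x)
}

#' Per-combination results of a pipeline run
#'
#' @param x A `mircombo_run`.
#' @param ... Unused.
#' @return The ranking tibble without list columns.
#' @export
tidy.mircombo_run <- function(x, ...) {
  out <- x$ranking
  out$fold_accuracies <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a pipeline run
#'
#' @param x A `mircombo_run`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts and the best combination.
#' @export
glance.mircombo_run <- function(x, ...) {
  counts <- x$counts
  counts$n_combos <- NULL # glance(ranking) reports it
  dplyr::bind_cols(tibble::as_tibble(counts), glance(x$ranking))
}

# fixed-format float, 6 significant digits, byte-stable
fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_tsv_plain <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a completed run to disk
#'
#' Writes `clusters.tsv` (membership, representative flag, loss
#' diagnostics), `combos.tsv` (the ranked combinations) and `report.json`
#' (configuration echo and stage counts). Floats are written with 6
#' significant digits; output is byte-stable for a given run.
#'
#' @param run A `mircombo_run`.
#' @param out_dir Output directory, created if needed.
#' @param benchmark Optional [compare_criteria()] table, written as
#'   `benchmark.tsv`.
#' @return The paths written, invisibly.
#' @export
write_report <- function(run, out_dir, benchmark = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  cl <- as_tibble(run$clusters)
  diag <- run$clusters$diagnostics
  if (is.null(diag)) {
    diag <- tibble::tibble(cluster_id = seq_along(run$clusters$members),
                           msl_prime = NA_real_, mlr = NA_real_)
  }
  cl <- dplyr::left_join(cl, diag[, c("cluster_id", "msl_prime", "mlr")],
                         by = "cluster_id")
  cl$is_representative <- cl$mirna_id %in% run$representatives$representative_id
  p <- file.path(out_dir, "clusters.tsv")
  write_tsv_plain(data.frame(
    mirna_id = cl$mirna_id, cluster_id = cl$cluster_id,
    is_representative = cl$is_representative,
    msl_prime = fmt6(cl$msl_prime), mlr = fmt6(cl$mlr)
  ), p)
  paths <- c(paths, p)

  rk <- run$ranking
  p <- file.path(out_dir, "combos.tsv")
  write_tsv_plain(data.frame(
    k = rk$k, rank = rk$rank, members = rk$members,
    sensitivity = fmt6(rk$sensitivity), specificity = fmt6(rk$specificity),
    total_accuracy = fmt6(rk$total_accuracy)
  ), p)
  paths <- c(paths, p)

  if (!is.null(benchmark)) {
    p <- file.path(out_dir, "benchmark.tsv")
    write_tsv_plain(data.frame(
      criterion = benchmark$criterion, k = benchmark$k, n = benchmark$n,
      avg_rank = fmt6(benchmark$avg_rank),
      hit_ratio = fmt6(benchmark$hit_ratio)
    ), p)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    config = run$config,
    counts = run$counts,
    representatives = run$representatives,
    best = glance(run$ranking)
  ), p, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
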