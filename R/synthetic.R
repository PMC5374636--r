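#' Specification for a synthetic two-class expression matrix
#'
#' Describes the generative model of [generate_synthetic()]: equicorrelated
#' Gaussian blocks of co-expressed miRNAs, an optional planted
#' class-discriminative member per block, and an optional planted
#' combination that is only jointly informative.
#'
#' @param n_clusters Number of co-expression blocks.
#' @param cluster_sizes Block sizes; a single integer is recycled.
#' @param within_cluster_correlation Pairwise correlation of rows within a
#'   block, in `[0, 1)`; default 0.8.
#' @param n0,n1 Samples per class; default 40 each.
#' @param planted_member Index within each block of the discriminative
#'   member, or `NULL` for no planted markers; default 1.
#' @param effect_size Between-class mean shift of each planted member, in
#'   units of the within-class standard deviation; default 3. Zero disables
#'   the shift (useful for null calibration).
#' @param noise_sd Within-class standard deviation of every row; default 1.
#' @param planted_combo Optional integer vector of block indices (length
#'   >= 2) whose planted members carry an XOR-style parity pattern instead
#'   of a mean shift: individually each looks like noise, jointly their sign
#'   pattern encodes the class.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `synth_spec` list, validated.
#' @export
synth_spec <- function(n_clusters = 5, cluster_sizes = 8,
                       within_cluster_correlation = 0.8,
                       n0 = 40, n1 = 40, planted_member = 1,
                       effect_size = 3, noise_sd = 1,
                       planted_combo = NULL, seed = 1) {
  cluster_sizes <- rep_len(as.integer(cluster_sizes), n_clusters)
  rho <- within_cluster_correlation
  if (rho < 0 || rho >= 1) stop("within_cluster_correlation must lie in [0, 1)", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (n0 < 2 || n1 < 2) stop("each class needs >= 2 samples", call. = FALSE)
  if (!is.null(planted_member) && any(planted_member > cluster_sizes)) {
    stop("planted_member exceeds a cluster size", call. = FALSE)
  }
  if (!is.null(planted_combo)) {
    if (length(planted_combo) < 2 || any(planted_combo > n_clusters)) {
      stop("planted_combo must name >= 2 valid clusters", call. = FALSE)
    }
    if (is.null(planted_member)) {
      stop("planted_combo needs planted_member to mark which rows carry it", call. = FALSE)
    }
  }
  structure(list(
    n_clusters = n_clusters, cluster_sizes = cluster_sizes,
    within_cluster_correlation = rho, n0 = n0, n1 = n1,
    planted_member = planted_member, effect_size = effect_size,
    noise_sd = noise_sd, planted_combo = planted_combo, seed = seed
  ), class = "synth_spec")
}

#' Generate a synthetic two-class expression matrix
#'
#' Each block draws a latent sample profile; member rows are
#' `noise_sd * (sqrt(rho) * latent + sqrt(1 - rho) * noise)`, giving every
#' pair of rows within a block correlation `rho` and every row marginal
#' standard deviation `noise_sd`. The planted member of each block gets a
#' between-class mean shift of `effect_size * noise_sd`; members of a
#' planted combination instead get `effect_size * noise_sd` times a random
#' sign whose parity across the combination encodes the class, so they are
#' jointly but not marginally informative.
#'
#' @param spec A [synth_spec()].
#' @return A list: `expr` ([expr_mat()]), `labels` (tibble), `truth` — a
#'   list with `blocks` (tibble `mirna_id`, `block`, `planted`,
#'   `in_planted_combo`) and `planted_combo` (sorted member ids or `NULL`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n0 + spec$n1
  p <- sum(spec$cluster_sizes)
  rho <- spec$within_cluster_correlation
  cls <- c(rep("c0", spec$n0), rep("c1", spec$n1))
  with_local_seed(spec$seed, {
    vals <- matrix(NA_real_, p, n)
    block_of <- integer(p)
    planted <- logical(p)
    row0 <- 0
    for (b in seq_len(spec$n_clusters)) {
      s <- spec$cluster_sizes[b]
      latent <- stats::rnorm(n)
      block <- sqrt(rho) * matrix(latent, s, n, byrow = TRUE) +
        sqrt(1 - rho) * matrix(stats::rnorm(s * n), s, n)
      vals[row0 + seq_len(s), ] <- spec$noise_sd * block
      block_of[row0 + seq_len(s)] <- b
      row0 <- row0 + s
    }
    block_start <- cumsum(c(0, spec$cluster_sizes[-spec$n_clusters]))
    delta <- spec$effect_size * spec$noise_sd
    combo_rows <- integer(0)
    if (!is.null(spec$planted_member)) {
      pm <- rep_len(spec$planted_member, spec$n_clusters)
      planted_rows <- block_start + pm
      planted[planted_rows] <- TRUE
      combo_blocks <- spec$planted_combo %||% integer(0)
      shift_blocks <- setdiff(seq_len(spec$n_clusters), combo_blocks)
      if (delta > 0) {
        for (b in shift_blocks) {
          r <- planted_rows[b]
          vals[r, cls == "c1"] <- vals[r, cls == "c1"] + delta
        }
        if (length(combo_blocks) >= 2) {
          combo_rows <- planted_rows[combo_blocks]
          t_len <- length(combo_rows)
          signs <- matrix(sample(c(-1, 1), (t_len - 1) * n, replace = TRUE),
                          t_len - 1, n)
          class_sign <- ifelse(cls == "c0", 1, -1)
          parity <- class_sign / apply(signs, 2, prod)
          all_signs <- rbind(signs, parity)
          for (i in seq_len(t_len)) {
            vals[combo_rows[i], ] <- vals[combo_rows[i], ] + delta * all_signs[i, ]
          }
        }
      }
    }
    rownames(vals) <- sprintf("mir-%03d", seq_len(p))
    colnames(vals) <- sprintf("s%03d", seq_len(n))
    expr <- expr_mat(vals)
    labels <- sample_labels(colnames(vals), cls)
    truth <- list(
      blocks = tibble::tibble(
        mirna_id = rownames(vals), block = block_of, planted = planted,
        in_planted_combo = seq_len(p) %in% combo_rows
      ),
      planted_combo = if (length(combo_rows)) sort(rownames(vals)[combo_rows])
    )
    list(expr = expr, labels = labels, truth = truth)
  })
}

#' Tiny hard-coded worked example
#'
#' A fixed 6-miRNA by 8-sample matrix (4 samples per class) with
#' hand-computed intermediates, used as a regression fixture: the Welch
#' statistic of the first row, the projection losses of the
#' `{mir-2, mir-3}` cluster under the direction `(1, 0)`, and a perfectly
#' correlated row pair.
#'
#' @return A list `expr`, `labels`, `expected` (named list of the
#'   hand-computed values).
#' @export
worked_example <- function() {
  vals <- rbind(
    `mir-1` = c(1, 2, 3, 4, 5, 6, 7, 8),
    `mir-2` = c(1, -1, 0, 0, 1, -1, 0, 0),
    `mir-3` = c(0, 0, 2, -2, 0, 0, 2, -2),
    `mir-4` = c(2, 1, 4, 3, 6, 5, 8, 7),
    `mir-5` = c(9, 7, 13, 11, 17, 15, 21, 19), # 2 * mir-4 + 5
    `mir-6` = c(5, 3, 4, 6, 2, 7, 1, 8)
  )
  colnames(vals) <- paste0("s", 1:8)
  labels <- sample_labels(colnames(vals), rep(c("c0", "c1"), each = 4))
  expected <- list(
    # mir-1: means 2.5 vs 6.5, both variances 5/3 on 4 samples
    welch_t_mir1 = -4 / sqrt(5 / 6),      # = -4.3817804600...
    welch_df_mir1 = 6,
    welch_p_mir1 = 2 * stats::pt(-4 / sqrt(5 / 6), 6),
    # cluster {mir-2, mir-3}, direction (1, 0): residual norms 0,0,2,2 twice
    msl_mir2_mir3 = 2,
    mlr_mir2_mir3 = 0.5,
    cor_dist_mir4_mir5 = 0
  )
  list(expr = expr_mat(vals), labels = labels, expected = expected)
}
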