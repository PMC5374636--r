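#' Fit the discriminant of one cluster
#'
#' Samples are the data points and the cluster's miRNAs the features: the
#' model is fitted on the samples-by-members submatrix. A cluster in which
#' the two classes have identical mean vectors has no discriminant direction;
#' callers treat such clusters as degenerate (kept unsplit, flagged).
#'
#' @param expr An [expr_mat()].
#' @param labels Sample labels ([sample_labels()]).
#' @param member_ids miRNA ids of the cluster.
#' @param ridge Passed to [fit_fda()].
#' @return An `fda_model` over the member features.
#' @export
cluster_fda <- function(expr, labels, member_ids, ridge = FALSE) {
  sub <- expr_subset(expr, member_ids)
  x <- t(sub$values) # samples x members
  fit_fda(x, align_classes(labels, expr), ridge = ridge)
}

#' Mean squared projection loss of a cluster
#'
#' Information lost when the samples (points in the cluster's feature space)
#' are collapsed onto the discriminant direction `w`: each centred sample is
#' projected onto the hyperplane through the sample mean with normal `w`,
#' and the mean squared length of those residuals is returned. A cluster
#' whose samples all lie on the line through the mean along `w` loses
#' nothing.
#'
#' @param x Numeric matrix, samples in rows, the cluster's `m` features in
#'   columns.
#' @param w Unit-length direction of length `m`.
#' @return Non-negative scalar; 0 whenever `m = 1`.
#' @examples
#' x <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
#' msl(x, c(1, 0)) # 2
#' @export
msl <- function(x, w) {
  x <- as.matrix(x)
  stopifnot(length(w) == ncol(x))
  ctr <- sweep(x, 2, colMeans(x))
  resid <- ctr - outer(drop(ctr %*% w), w)
  mean(rowSums(resid^2))
}

#' Mean loss rate of a cluster
#'
#' Relative counterpart of [msl()]: the residual length of each sample is
#' divided by the norm of the raw (uncentred) sample, and the ratios are
#' averaged. Samples of zero norm are excluded from the average; if every
#' sample has zero norm the rate is 0 with a warning.
#'
#' @inheritParams msl
#' @return Non-negative scalar; 0 whenever `m = 1`.
#' @examples
#' x <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
#' mlr(x, c(1, 0)) # 0.5
#' @export
mlr <- function(x, w) {
  x <- as.matrix(x)
  stopifnot(length(w) == ncol(x))
  ctr <- sweep(x, 2, colMeans(x))
  resid <- ctr - outer(drop(ctr %*% w), w)
  rnorm_ <- sqrt(rowSums(resid^2))
  xnorm <- sqrt(rowSums(x^2))
  ok <- xnorm > 0
  if (!any(ok)) {
    warning("all samples have zero norm; mean loss rate undefined, returning 0")
    return(0)
  }
  mean(rnorm_[ok] / xnorm[ok])
}

# Internal: loss diagnostics for one cluster
cluster_loss <- function(expr, labels, member_ids, ridge = FALSE) {
  m <- length(member_ids)
  if (m == 1) {
    return(list(m = 1, msl = 0, msl_prime = 0, mlr = 0,
                mlr_threshold = 0, degenerate = FALSE, model = NULL))
  }
  x <- t(expr_subset(expr, member_ids)$values)
  model <- tryCatch(fit_fda(x, align_classes(labels, expr), ridge = ridge),
                    error = function(e) NULL)
  if (is.null(model)) {
    return(list(m = m, msl = NA_real_, msl_prime = NA_real_, mlr = NA_real_,
                mlr_threshold = 1 - 1 / m^2, degenerate = TRUE, model = NULL))
  }
  msl_val <- msl(x, model$w)
  list(m = m, msl = msl_val, msl_prime = msl_val / m, mlr = mlr(x, model$w),
       mlr_threshold = 1 - 1 / m^2, degenerate = FALSE, model = model)
}

#' Refine raw clusters by projection-loss criteria
#'
#' Each cluster is judged by two measures of how much of its structure a
#' single discriminant direction captures: the size-normalised mean squared
#' loss `MSL' = MSL / m` and the mean loss rate MLR (see [msl()], [mlr()];
#' `m` is the cluster size). A cluster is split whenever either criterion is
#' violated — `MSL' > msl_threshold` or `MLR > 1 - 1/m^2` — by cutting its
#' dendrogram subtree at its top merge into the two child subtrees and
#' recursing. Singletons are always accepted, as are clusters whose
#' discriminant is degenerate (identical class means in the member
#' subspace), which are flagged rather than split along a meaningless
#' direction.
#'
#' @param raw A `cluster_set` from [cut_by_inconsistency()] (clusters must
#'   correspond to dendrogram subtrees).
#' @param expr An [expr_mat()] restricted to the clustered miRNAs.
#' @param labels Sample labels.
#' @param msl_threshold Cutoff on `MSL'`; default 0.65, the point of steepest
#'   ascent of the sorted `MSL'` curve on typical miRNA data (inspect yours
#'   with [plot_msl_curve()]).
#' @param ridge Passed to [fit_fda()].
#' @return A `cluster_set` whose `diagnostics` tibble has one row per final
#'   cluster: `cluster_id`, `m`, `msl`, `msl_prime`, `mlr`, `mlr_threshold`,
#'   `degenerate`.
#' @export
refine_clusters <- function(raw, expr, labels, msl_threshold = 0.65,
                            ridge = FALSE) {
  dend <- raw$dend
  refine_one <- function(members, node) {
    d <- cluster_loss(expr, labels, members, ridge = ridge)
    splittable <- !is.null(dend) && !is.null(node) && !is.na(node) && node > 0
    fails <- !d$degenerate && d$m > 1 &&
      (d$msl_prime > msl_threshold || d$mlr > d$mlr_threshold)
    if (fails && !splittable) {
      stop("cluster fails the loss criteria but has no dendrogram subtree to split",
           call. = FALSE)
    }
    if (!fails) {
      return(list(list(members = members, node = node, diag = d)))
    }
    kids <- dend$merge[node, ]
    unlist(lapply(kids, function(k) {
      refine_one(node_leaves(dend, k), k)
    }), recursive = FALSE)
  }
  nodes <- raw$nodes
  if (is.null(nodes)) nodes <- rep(NA_integer_, length(raw$members))
  out <- unlist(lapply(seq_along(raw$members), function(i) {
    refine_one(raw$members[[i]], nodes[[i]])
  }), recursive = FALSE)
  diags <- dplyr::bind_rows(lapply(seq_along(out), function(i) {
    d <- out[[i]]$diag
    tibble::tibble(cluster_id = i, m = d$m, msl = d$msl,
                   msl_prime = d$msl_prime, mlr = d$mlr,
                   mlr_threshold = d$mlr_threshold, degenerate = d$degenerate)
  }))
  cluster_set(lapply(out, `[[`, "members"),
              nodes = vapply(out, function(o) {
                n <- o$node
                if (is.null(n) || is.na(n)) NA_integer_ else as.integer(n)
              }, integer(1)),
              dend = dend, diagnostics = diags)
}
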