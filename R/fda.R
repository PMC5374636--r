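#' Fit Fisher's linear discriminant
#'
#' Finds the projection direction `w` proportional to `Sw^-1 (m0 - m1)`,
#' where `Sw` is the within-class scatter matrix (sum over both classes of
#' outer products of mean-centred samples) and `m0`, `m1` the class mean
#' vectors. When `Sw` is singular — inevitable when the number of features
#' exceeds the number of samples — the Moore-Penrose pseudo-inverse gives the
#' minimum-norm direction; alternatively a small ridge `Sw + lambda I` with
#' `lambda = 1e-6 * trace(Sw)/d` can be requested. `w` is scaled to unit
#' Euclidean norm with the sign fixed so that `w' (m0 - m1) >= 0`, which
#' makes the decision rule "projection >= threshold means class c0"
#' coherent. The threshold is the class-size-weighted mean of the projected
#' class means, `y0 = (n0 m0' + n1 m1')/(n0 + n1)`.
#'
#' @param data Numeric matrix, samples in rows, the `d` features in columns
#'   (note: this is the transpose of the expression matrix orientation).
#' @param classes Factor of length `nrow(data)` with two levels; the first
#'   level is class c0. A labels tibble from [sample_labels()] is also
#'   accepted when `data` rows are named by sample id.
#' @param ridge Use ridge regularisation instead of the pseudo-inverse?
#' @return An object of class `fda_model` with elements `feature_ids`, `w`
#'   (unit length), `m0_vec`, `m1_vec`, `Sw`, `m0_proj`, `m1_proj`, `y0`,
#'   `n0`, `n1`.
#' @examples
#' x <- matrix(c(0, 2, 4, 6), ncol = 1)
#' fit_fda(x, factor(c("a", "a", "b", "b"), levels = c("a", "b")))
#' @export
fit_fda <- function(data, classes, ridge = FALSE) {
  data <- as.matrix(data)
  if (ncol(data) < 1) stop("need at least one feature", call. = FALSE)
  if (is.data.frame(classes)) {
    idx <- match(rownames(data), classes$sample_id)
    if (anyNA(idx)) stop("data rownames must match label sample ids", call. = FALSE)
    classes <- classes$class[idx]
  }
  classes <- as.factor(classes)
  if (nlevels(classes) != 2) stop("exactly two classes required", call. = FALSE)
  i0 <- classes == levels(classes)[1]
  n0 <- sum(i0); n1 <- sum(!i0)
  if (n0 < 2 || n1 < 2) stop("each class needs >= 2 samples", call. = FALSE)
  x0 <- data[i0, , drop = FALSE]
  x1 <- data[!i0, , drop = FALSE]
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  if (all(m0 == m1)) {
    stop("degenerate discriminant: identical class means", call. = FALSE)
  }
  c0 <- sweep(x0, 2, m0)
  c1 <- sweep(x1, 2, m1)
  Sw <- crossprod(c0) + crossprod(c1)
  Sw <- (Sw + t(Sw)) / 2
  d <- ncol(data)
  if (ridge) {
    Sinv <- solve(Sw + diag(1e-6 * sum(diag(Sw)) / d, d))
  } else {
    Sinv <- MASS::ginv(Sw)
  }
  w <- drop(Sinv %*% (m0 - m1))
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    # pseudo-inverse annihilated the mean difference (it lies outside the
    # scatter's row space only when Sw = 0); fall back to the difference itself
    w <- m0 - m1
    nw <- sqrt(sum(w^2))
  }
  w <- w / nw
  if (sum(w * (m0 - m1)) < 0) w <- -w
  m0p <- sum(w * m0)
  m1p <- sum(w * m1)
  structure(list(
    feature_ids = colnames(data), w = w, m0_vec = m0, m1_vec = m1, Sw = Sw,
    m0_proj = m0p, m1_proj = m1p,
    y0 = (n0 * m0p + n1 * m1p) / (n0 + n1),
    n0 = n0, n1 = n1,
    classes = levels(classes)
  ), class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf("<fda_model> d = %d, y0 = %.4g, projected means %.4g / %.4g\n",
              length(x$w), x$y0, x$m0_proj, x$m1_proj))
  invisible(x)
}

#' Project samples onto a fitted discriminant direction
#'
#' @param model An [fit_fda()] result.
#' @param x Numeric vector of length `d`, or a matrix with `d` columns
#'   (one sample per row).
#' @return The scalar projection(s) `w' x`.
#' @export
fda_project <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w)) stop("feature count mismatch", call. = FALSE)
    return(drop(x %*% model$w))
  }
  if (length(x) != length(model$w)) stop("feature count mismatch", call. = FALSE)
  sum(model$w * x)
}

#' Classify samples with a fitted discriminant
#'
#' A sample whose projection is greater than or equal to the threshold `y0`
#' is assigned to class c0, otherwise to c1.
#'
#' @inheritParams fda_project
#' @return Factor of predicted classes with the model's class levels.
#' @export
fda_classify <- function(model, x) {
  y <- fda_project(model, x)
  factor(ifelse(y >= model$y0, model$classes[1], model$classes[2]),
         levels = model$classes)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted discriminant into per-feature weights
#'
#' @param x An `fda_model`.
#' @param ... Unused.
#' @return A tibble `feature_id`, `weight`, `abs_weight`, sorted by the input
#'   feature order.
#' @export
tidy.fda_model <- function(x, ...) {
  tibble::tibble(
    feature_id = x$feature_ids %||% paste0("f", seq_along(x$w)),
    weight = x$w,
    abs_weight = abs(x$w)
  )
}

#' One-row summary of a fitted discriminant
#'
#' @param x An `fda_model`.
#' @param ... Unused.
#' @return A one-row tibble with the dimension, class sizes, projected class
#'   means, their separation, and the decision threshold.
#' @export
glance.fda_model <- function(x, ...) {
  tibble::tibble(
    d = length(x$w), n0 = x$n0, n1 = x$n1,
    m0_proj = x$m0_proj, m1_proj = x$m1_proj,
    separation = x$m0_proj - x$m1_proj, y0 = x$y0
  )
}
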