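# A two-feature cluster whose samples need two directions: feature 1 carries
# the class signal, feature 2 carries large class-independent structure.
orthogonal_cluster <- function(n0 = 30, n1 = 30, seed = 101) {
  set.seed(seed)
  n <- n0 + n1
  f1 <- c(rnorm(n0, -2, 0.5), rnorm(n1, 2, 0.5))
  f2 <- rnorm(n, 0, 4)
  vals <- rbind(`mir-a` = f1, `mir-b` = f2)
  colnames(vals) <- sprintf("s%02d", 1:n)
  x <- expr_mat(vals)
  list(expr = x, labels = labels_for(x, n0))
}

test_that("msl and mlr reproduce the four-sample hand example", {
  x <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  expect_equal(msl(x, c(1, 0)), 2)
  expect_equal(mlr(x, c(1, 0)), 0.5)
})

test_that("projection loss vanishes when a single direction captures the data", {
  # all samples on the line through the mean along w
  w <- c(3, 4) / 5
  x <- outer(c(-2, -1, 0, 1, 2), w) + 7
  expect_equal(msl(x, w), 0, tolerance = 1e-12)
  expect_equal(mlr(x, w), 0, tolerance = 1e-12)
  # constant data: every sample equals the mean
  expect_equal(msl(matrix(5, 4, 2), c(1, 0)), 0)
  # one dimension: residuals are identically zero
  expect_equal(msl(matrix(rnorm(6), ncol = 1), 1), 0, tolerance = 1e-12)
  expect_equal(mlr(matrix(rnorm(6), ncol = 1), 1), 0, tolerance = 1e-12)
})

test_that("msl obeys its translation and scaling laws", {
  set.seed(31)
  x <- matrix(rnorm(40), 10, 4)
  w <- rnorm(4); w <- w / sqrt(sum(w^2))
  base <- msl(x, w)
  expect_equal(msl(sweep(x, 2, c(5, -2, 0.5, 9), `+`), w), base,
               tolerance = 1e-10)
  expect_equal(msl(3 * x, w), 9 * base, tolerance = 1e-10)
})

test_that("zero-norm samples are excluded from the loss rate", {
  x <- rbind(c(0, 0), c(2, 2), c(2, -2), c(-4, 0))
  # mean (0,0); sample 1 has zero norm and is skipped
  expect_equal(mlr(x, c(1, 0)),
               mean(c(2 / sqrt(8), 2 / sqrt(8), 0 / 4)))
  expect_warning(val <- mlr(matrix(0, 3, 2), c(1, 0)), "zero norm")
  expect_equal(val, 0)
})

test_that("cluster_fda fits on the samples-by-members submatrix", {
  sim <- separable_expr(n_noise = 2)
  m <- cluster_fda(sim$expr, sim$labels, c("mir-sep", "mir-n01", "mir-n02"))
  expect_s3_class(m, "fda_model")
  # only the separating feature matters: its weight dominates
  expect_equal(which.max(abs(m$w)), 1L)
  single <- cluster_fda(sim$expr, sim$labels, "mir-sep")
  expect_equal(abs(unname(single$w)), 1)
  # duplicated member rows -> singular scatter, pseudo-inverse path
  vals <- sim$expr$values[c(1, 1, 2), ]
  rownames(vals) <- c("a", "b", "c")
  dup <- expr_mat(vals)
  md <- cluster_fda(dup, sim$labels, c("a", "b", "c"))
  expect_true(all(is.finite(md$w)))
})

test_that("a cluster mixing orthogonal structure is split and the children pass", {
  oc <- orthogonal_cluster()
  dend <- average_linkage(expr_dist(oc$expr, "euclidean"))
  raw <- cut_by_inconsistency(dend, threshold = 10) # force one raw cluster
  expect_equal(length(raw), 1L)
  refined <- refine_clusters(raw, oc$expr, oc$labels, msl_threshold = 0.65)
  expect_gt(length(refined), 1L)
  d <- refined$diagnostics
  ok <- d$degenerate | (d$msl_prime <= 0.65 & d$mlr <= d$mlr_threshold)
  expect_true(all(ok))
})

test_that("clusters that already pass are returned unchanged", {
  # tight equicorrelated block with a class shift: one direction suffices
  set.seed(41)
  sim <- generate_synthetic(synth_spec(n_clusters = 2, cluster_sizes = 4,
                                       within_cluster_correlation = 0.95,
                                       n0 = 25, n1 = 25, effect_size = 2,
                                       seed = 41))
  dend <- average_linkage(expr_dist(sim$expr))
  raw <- cut_by_inconsistency(dend, 1)
  refined <- refine_clusters(raw, sim$expr, sim$labels, msl_threshold = 2)
  # permissive threshold and tight blocks: nothing to split
  expect_equal(length(refined), length(raw))
  expect_equal(refined$members, raw$members)
  expect_equal(nrow(refined$diagnostics), length(raw))
})

test_that("singletons always pass with zero losses", {
  cs <- trivial_clusters(c("mir-sep", "mir-n01"))
  sim <- separable_expr(n_noise = 1)
  refined <- refine_clusters(cs, sim$expr, sim$labels)
  expect_equal(length(refined), 2L)
  expect_equal(refined$diagnostics$msl_prime, c(0, 0))
  expect_equal(refined$diagnostics$mlr, c(0, 0))
  expect_equal(refined$diagnostics$mlr_threshold, c(0, 0))
})

test_that("refinement never merges and terminates on recursive splits", {
  set.seed(51)
  sim <- generate_synthetic(synth_spec(n_clusters = 3, cluster_sizes = 6,
                                       within_cluster_correlation = 0.3,
                                       n0 = 20, n1 = 20, seed = 51))
  dend <- average_linkage(expr_dist(sim$expr))
  raw <- cut_by_inconsistency(dend, 2)
  refined <- refine_clusters(raw, sim$expr, sim$labels, msl_threshold = 0.1)
  expect_gte(length(refined), length(raw))
  expect_setequal(unlist(refined$members), unlist(raw$members))
  d <- refined$diagnostics
  expect_true(all(d$degenerate |
                    (d$msl_prime <= 0.1 & d$mlr <= d$mlr_threshold)))
})
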