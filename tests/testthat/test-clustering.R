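three_point_dend <- function() {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  average_linkage(stats::as.dist(d))
}

test_that("correlation distance reflects co-expression, euclidean reflects geometry", {
  base <- c(1, 2, 3, 5, 4, 6)
  vals <- rbind(r = base, scaled = 2 * base + 5, flipped = -base,
                other = c(2, 2, 1, 3, 1, 4))
  colnames(vals) <- paste0("s", 1:6)
  x <- expr_mat(vals)
  d <- as.matrix(expr_dist(x, "correlation"))
  expect_equal(d["r", "scaled"], 0, tolerance = 1e-12)
  expect_equal(d["r", "flipped"], 2, tolerance = 1e-12)
  vals2 <- rbind(a = base, b = base, c = base + 1)
  colnames(vals2) <- paste0("s", 1:6)
  de <- as.matrix(expr_dist(expr_mat(vals2), "euclidean"))
  expect_equal(de["a", "b"], 0)
  expect_equal(de["a", "c"], sqrt(6))
})

test_that("zero-variance rows are rejected under the correlation metric by name", {
  vals <- rbind(flat = rep(2, 4), ok = 1:4)
  colnames(vals) <- paste0("s", 1:4)
  expect_error(expr_dist(expr_mat(vals), "correlation"), "flat")
})

test_that("average linkage agglomerates the hand example in order", {
  dend <- three_point_dend()
  expect_equal(dend$height, c(1, 4))
  expect_setequal(node_leaves_for_test(dend, 1), c("A", "B"))
  expect_setequal(node_leaves_for_test(dend, 2), c("A", "B", "C"))
  # two points: a single merge at their distance
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(average_linkage(d2)$height, 3)
  expect_error(average_linkage(stats::as.dist(matrix(c(0, NA, NA, 0), 2))),
               "non-finite")
})

test_that("average linkage uses the size-weighted mean of member distances", {
  # 4 leaves: {A,B} merge at 1; C at distance 2 from A, 6 from B -> d({AB},C) = 4
  m <- matrix(c(0, 1, 2, 9,
                1, 0, 6, 9,
                2, 6, 0, 9,
                9, 9, 9, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dend <- average_linkage(stats::as.dist(m))
  expect_equal(dend$height, c(1, 4, 9))
})

test_that("equal distances give equal merge heights", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  dimnames(m) <- list(LETTERS[1:4], LETTERS[1:4])
  dend <- average_linkage(stats::as.dist(m))
  expect_equal(dend$height, rep(1, 3))
})

test_that("inconsistency matches the hand-computed coefficients", {
  dend <- three_point_dend()
  coefs <- inconsistency(dend, depth = 2)
  expect_equal(coefs[1], 0) # leaf-adjacent link, no links beneath
  expect_equal(coefs[2], (4 - 2.5) / stats::sd(c(4, 1)), tolerance = 1e-12)
  expect_equal(coefs[2], 0.7071068, tolerance = 1e-6)
  # depth 1 compares each link only with itself -> all zero
  expect_equal(inconsistency(dend, depth = 1), c(0, 0))
})

test_that("cutting by inconsistency yields the expected partitions", {
  dend <- three_point_dend()
  all_in_one <- cut_by_inconsistency(dend, threshold = 1)
  expect_equal(length(all_in_one), 1L)
  singles <- cut_by_inconsistency(dend, threshold = -0.1)
  expect_equal(length(singles), 3L)
  expect_true(all(lengths(singles$members) == 1))
  half <- cut_by_inconsistency(dend, threshold = 0.5)
  expect_equal(sort(vapply(half$members, paste, "", collapse = "+")),
               c("A+B", "C"))
})

test_that("every cut is a partition and cluster count decreases with threshold", {
  set.seed(12)
  sim <- generate_synthetic(synth_spec(n_clusters = 4, cluster_sizes = 5,
                                       n0 = 15, n1 = 15, seed = 12))
  dend <- average_linkage(expr_dist(sim$expr, "correlation"))
  counts <- vapply(c(-1, 0, 0.3, 0.7, 1, 1.5, 3), function(thr) {
    cs <- cut_by_inconsistency(dend, thr)
    ids <- sort(unlist(cs$members))
    expect_equal(ids, sort(mirna_ids(sim$expr))) # disjoint + exhaustive
    length(cs)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(13)
  sim <- generate_synthetic(synth_spec(n_clusters = 3, cluster_sizes = 4,
                                       n0 = 20, n1 = 20, seed = 13))
  cs1 <- cut_by_inconsistency(average_linkage(expr_dist(sim$expr)), 1)
  perm <- sample(mirna_ids(sim$expr))
  cs2 <- cut_by_inconsistency(
    average_linkage(expr_dist(expr_subset(sim$expr, perm))), 1)
  canon <- function(cs) sort(vapply(cs$members,
                                    function(m) paste(sort(m), collapse = "+"),
                                    ""))
  expect_equal(canon(cs1), canon(cs2))
})

test_that("newick export round-trips through ape with the right tips and depths", {
  dend <- three_point_dend()
  nwk <- dend_newick(dend)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(depths), 4) # root-to-leaf distance equals the top height
})

test_that("trivial clustering makes one singleton per miRNA", {
  cs <- trivial_clusters(c("a", "b", "c"))
  expect_equal(length(cs), 3L)
  expect_true(all(lengths(cs$members) == 1))
  expect_error(cluster_set(list(c("a", "b"), "a")), "overlap")
  expect_error(cluster_set(list(character(0))), "empty")
})
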