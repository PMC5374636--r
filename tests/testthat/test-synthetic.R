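test_that("generation is a pure function of the spec", {
  spec <- synth_spec(n_clusters = 3, cluster_sizes = 4, n0 = 10, n1 = 10,
                     seed = 99)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  c <- generate_synthetic(synth_spec(n_clusters = 3, cluster_sizes = 4,
                                     n0 = 10, n1 = 10, seed = 100))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("spec validation rejects infeasible settings", {
  expect_error(synth_spec(within_cluster_correlation = 1), "correlation")
  expect_error(synth_spec(effect_size = -1), "effect_size")
  expect_error(synth_spec(noise_sd = 0), "noise_sd")
  expect_error(synth_spec(planted_member = 9, cluster_sizes = 8), "planted_member")
  expect_error(synth_spec(planted_combo = 1), "planted_combo")
  expect_error(synth_spec(planted_combo = c(1, 7), n_clusters = 5), "planted_combo")
})

test_that("realized within-block correlations match the request", {
  sim <- generate_synthetic(synth_spec(n_clusters = 3, cluster_sizes = 6,
                                       within_cluster_correlation = 0.7,
                                       n0 = 50, n1 = 50, effect_size = 0,
                                       seed = 7))
  for (b in 1:3) {
    rows <- sim$truth$blocks$mirna_id[sim$truth$blocks$block == b]
    cm <- stats::cor(t(sim$expr$values[rows, ]))
    off <- cm[upper.tri(cm)]
    expect_lt(abs(mean(off) - 0.7), 0.1)
    expect_gt(min(off), 0.4)
  }
  # across blocks the correlation is near zero
  r1 <- sim$truth$blocks$mirna_id[sim$truth$blocks$block == 1][1]
  r2 <- sim$truth$blocks$mirna_id[sim$truth$blocks$block == 2][1]
  expect_lt(abs(stats::cor(sim$expr$values[r1, ], sim$expr$values[r2, ])), 0.35)
})

test_that("planted members carry the requested effect and dominate their block", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    sim <- generate_synthetic(synth_spec(n_clusters = 4, cluster_sizes = 6,
                                         within_cluster_correlation = 0.5,
                                         n0 = 40, n1 = 40, effect_size = 3,
                                         seed = 200 + s))
    scr <- ttest_screen(sim$expr, sim$labels, alpha = 0.999999)
    pv <- stats::setNames(scr$p, scr$mirna_id)
    for (b in 1:4) {
      blk <- sim$truth$blocks[sim$truth$blocks$block == b, ]
      total <- total + 1
      if (blk$mirna_id[which.min(pv[blk$mirna_id])] ==
            blk$mirna_id[blk$planted]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("the inconsistency cut refines correlated blocks without mixing them", {
  # At depth 2 the coefficient is bounded by 2/sqrt(3) ~ 1.155, and balanced
  # merges inside an exchangeable block approach that bound, so a threshold-1
  # cut splits blocks into pure fragments rather than recovering them
  # exactly; the honest recovery property is purity plus a high Rand index.
  rand_index <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    agree <- sum(choose(tab, 2))
    (choose(n, 2) + 2 * agree - sum(choose(rowSums(tab), 2)) -
       sum(choose(colSums(tab), 2))) / choose(n, 2)
  }
  ris <- vapply(1:10, function(s) {
    sim <- generate_synthetic(synth_spec(n_clusters = 5, cluster_sizes = 8,
                                         within_cluster_correlation = 0.9,
                                         n0 = 30, n1 = 30, effect_size = 0,
                                         seed = 300 + s))
    cs <- cut_by_inconsistency(average_linkage(expr_dist(sim$expr)), 1)
    memb <- tibble::as_tibble(cs)
    truth <- sim$truth$blocks
    m <- memb$cluster_id[match(truth$mirna_id, memb$mirna_id)]
    # purity: no cluster straddles two blocks
    expect_true(all(vapply(split(truth$block, m),
                           function(x) length(unique(x)) == 1, logical(1))))
    rand_index(m, truth$block)
  }, numeric(1))
  expect_gte(mean(ris), 0.85)
  expect_gte(mean(ris >= 0.85), 0.8)
})

test_that("an XOR-planted combination is jointly but not marginally informative", {
  sim <- generate_synthetic(synth_spec(n_clusters = 3, cluster_sizes = 3,
                                       within_cluster_correlation = 0.2,
                                       n0 = 50, n1 = 50, effect_size = 4,
                                       planted_combo = c(1, 2), seed = 88))
  combo <- sim$truth$planted_combo
  expect_equal(length(combo), 2)
  scr <- ttest_screen(sim$expr, sim$labels, alpha = 0.999999)
  pv <- stats::setNames(scr$p, scr$mirna_id)
  expect_true(all(pv[combo] > 0.01)) # no marginal mean shift
  joint <- score_combo(sim$expr, sim$labels, combo, folds = 5, seed = 1)
  expect_gte(joint$total_accuracy, 0.85)
  solo <- score_combo(sim$expr, sim$labels, combo[1], folds = 5, seed = 1)
  expect_lte(solo$total_accuracy, 0.7)
})

test_that("the worked example reproduces its hand-computed intermediates", {
  wx <- worked_example()
  expect_identical(wx$expr$values, worked_example()$expr$values) # byte-stable
  exp <- wx$expected
  cls <- wx$labels$class
  w <- welch_test(wx$expr$values["mir-1", cls == "c0"],
                  wx$expr$values["mir-1", cls == "c1"])
  expect_equal(w$t, exp$welch_t_mir1, tolerance = 1e-10)
  expect_equal(w$df, exp$welch_df_mir1, tolerance = 1e-10)
  expect_equal(w$p, exp$welch_p_mir1, tolerance = 1e-10)
  sub <- t(wx$expr$values[c("mir-2", "mir-3"), ])
  expect_equal(msl(sub, c(1, 0)), exp$msl_mir2_mir3)
  expect_equal(mlr(sub, c(1, 0)), exp$mlr_mir2_mir3)
  d <- as.matrix(expr_dist(wx$expr, "correlation"))
  expect_equal(d["mir-4", "mir-5"], exp$cor_dist_mir4_mir5, tolerance = 1e-12)
})
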