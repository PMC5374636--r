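# Shared fixture builders; everything is generated in code.

# Tiny well-formed expression TSV on disk; returns the path.
write_toy_expr <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  writeLines(c(
    "id\ts1\ts2",
    "mir-a\t1.5\t2.5",
    "mir-b\t3\tNA",
    "mir-c\t-1\t0"
  ), path)
  path
}

# Two-class matrix with one cleanly separating row and pure-noise rows.
separable_expr <- function(n0 = 20, n1 = 20, n_noise = 3, gap = 10, seed = 42) {
  set.seed(seed)
  n <- n0 + n1
  sep <- c(rnorm(n0, 0, 0.5), rnorm(n1, gap, 0.5))
  noise <- matrix(rnorm(n_noise * n), n_noise, n)
  vals <- rbind(sep, noise)
  rownames(vals) <- c("mir-sep", sprintf("mir-n%02d", seq_len(n_noise)))
  colnames(vals) <- sprintf("s%03d", seq_len(n))
  list(
    expr = expr_mat(vals),
    labels = sample_labels(colnames(vals), rep(c("c0", "c1"), c(n0, n1)))
  )
}

node_leaves_for_test <- function(dend, node) {
  mircombo:::node_leaves(dend, node)
}

# Labels tibble for an arbitrary matrix, first n0 columns class c0.
labels_for <- function(expr, n0) {
  n <- length(sample_ids(expr))
  sample_labels(sample_ids(expr), rep(c("c0", "c1"), c(n0, n - n0)))
}
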