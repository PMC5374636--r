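#' Distance matrix between miRNA expression profiles
#'
#' Correlation distance `1 - Pearson r` between rows (so perfectly
#' co-expressed miRNAs are at distance 0 and anti-correlated ones at 2), or
#' plain Euclidean row distance.
#'
#' @param expr An [expr_mat()] with at least two rows.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return A [stats::dist] object over the miRNAs.
#' @export
expr_dist <- function(expr, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  v <- expr$values
  if (nrow(v) < 2) stop("need at least two miRNAs to cluster", call. = FALSE)
  if (metric == "euclidean") return(stats::dist(v, method = "euclidean"))
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance row(s) under correlation metric: ",
         paste(rownames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::as.dist(1 - stats::cor(t(v)))
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA-style agglomeration: repeatedly merge the closest pair of clusters,
#' with the distance between two clusters the unweighted mean of all
#' member-pair distances. Merge heights are non-decreasing from the leaves to
#' the root.
#'
#' @param dist A [stats::dist] object (all distances finite).
#' @return A `mir_dendrogram`: the merge table (`merge`, `height` as in
#'   [stats::hclust]) plus `leaf_ids`.
#' @export
average_linkage <- function(dist) {
  if (any(!is.finite(dist))) stop("non-finite distances", call. = FALSE)
  hc <- stats::hclust(dist, method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 order = hc$order, hclust = hc),
            class = "mir_dendrogram")
}

#' @export
print.mir_dendrogram <- function(x, ...) {
  cat(sprintf("<mir_dendrogram> %d leaves, heights [%.4g, %.4g]\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

# Internal: leaf labels under a node (hclust encoding: negative = leaf index,
# positive = merge-row index)
node_leaves <- function(dend, node) {
  if (node < 0) return(dend$labels[-node])
  unlist(lapply(dend$merge[node, ], node_leaves, dend = dend))
}

#' Inconsistency coefficient of every dendrogram link
#'
#' For each merge link, consider the links within `depth` levels beneath it
#' (itself at level 1, its child links at level 2, and so on) and standardise
#' the link's height against that set: `(height - mean) / sd` with the sample
#' standard deviation. A link whose comparison set has zero spread (for
#' example a link joining two leaves) gets coefficient 0. Links whose height
#' far exceeds the links below them mark natural cluster borders.
#'
#' @param dend A [average_linkage()] dendrogram.
#' @param depth Number of levels to look down; default 2.
#' @return Numeric vector, one coefficient per merge link, in merge order.
#' @export
inconsistency <- function(dend, depth = 2) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  n_links <- nrow(dend$merge)
  collect <- function(link, d) {
    if (d <= 0) return(integer(0))
    kids <- dend$merge[link, ]
    c(link, unlist(lapply(kids[kids > 0], collect, d = d - 1)))
  }
  vapply(seq_len(n_links), function(j) {
    hs <- dend$height[collect(j, depth)]
    if (length(hs) < 2) return(0)
    s <- stats::sd(hs)
    if (s == 0) 0 else (dend$height[j] - mean(hs)) / s
  }, numeric(1))
}

#' Cut a dendrogram into raw clusters by inconsistency
#'
#' A link is consistent when its inconsistency coefficient is at most
#' `threshold` and every link beneath it is consistent too. The maximal
#' consistent subtrees become clusters; any leaf not under a consistent link
#' becomes a singleton cluster. Cluster ids are assigned in leaf order of the
#' first member.
#'
#' @param dend A [average_linkage()] dendrogram.
#' @param threshold Inconsistency cutoff; default 1.
#' @param depth Depth passed to [inconsistency()]; default 2.
#' @return A `cluster_set` (see [cluster_set()]).
#' @export
cut_by_inconsistency <- function(dend, threshold = 1, depth = 2) {
  n_links <- nrow(dend$merge)
  coef <- inconsistency(dend, depth)
  consistent <- logical(n_links)
  for (j in seq_len(n_links)) { # merge order is bottom-up
    kids <- dend$merge[j, ]
    kids_ok <- all(consistent[kids[kids > 0]])
    consistent[j] <- coef[j] <= threshold && kids_ok
  }
  parent <- integer(n_links) # 0 = root
  for (j in seq_len(n_links)) {
    kids <- dend$merge[j, ]
    parent[kids[kids > 0]] <- j
  }
  roots <- which(consistent & (parent == 0 | !consistent[pmax(parent, 1)]))
  nodes <- as.integer(roots)
  # leaves not under any consistent link: their merge row is inconsistent
  leaf_parent <- integer(length(dend$labels))
  for (j in seq_len(n_links)) {
    kids <- dend$merge[j, ]
    leaf_parent[-kids[kids < 0]] <- j
  }
  singles <- which(!consistent[leaf_parent])
  nodes <- c(nodes, -as.integer(singles))
  members <- lapply(nodes, node_leaves, dend = dend)
  ord <- order(vapply(members, function(m) min(match(m, dend$labels)), integer(1)))
  cluster_set(members[ord], nodes = nodes[ord], dend = dend)
}

#' Build a cluster set
#'
#' A partition of miRNA ids into non-empty, disjoint clusters. Usually
#' produced by [cut_by_inconsistency()] or [refine_clusters()];
#' [trivial_clusters()] builds the one-miRNA-per-cluster partition.
#'
#' @param members List of character vectors of miRNA ids.
#' @param nodes Optional dendrogram node per cluster (hclust encoding), used
#'   by [refine_clusters()] to split along the tree.
#' @param dend Optional originating [average_linkage()] dendrogram.
#' @param diagnostics Optional tibble of per-cluster loss diagnostics.
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(members, nodes = NULL, dend = NULL, diagnostics = NULL) {
  if (length(members) == 0) stop("empty cluster set", call. = FALSE)
  if (any(lengths(members) == 0)) stop("empty cluster", call. = FALSE)
  ids <- unlist(members)
  if (anyDuplicated(ids)) stop("clusters overlap", call. = FALSE)
  structure(list(members = members, nodes = nodes, dend = dend,
                 diagnostics = diagnostics),
            class = "cluster_set")
}

#' @rdname cluster_set
#' @param ids miRNA ids, one singleton cluster each.
#' @export
trivial_clusters <- function(ids) {
  cluster_set(as.list(ids))
}

#' @export
length.cluster_set <- function(x) length(x$members)

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d miRNAs (sizes %s)\n",
              length(x$members), length(unlist(x$members)),
              paste(range(lengths(x$members)), collapse = "-")))
  invisible(x)
}

#' @export
as_tibble.cluster_set <- function(x, ...) {
  tibble::tibble(
    mirna_id = unlist(x$members),
    cluster_id = rep(seq_along(x$members), lengths(x$members))
  )
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights (ultrametric tree); meant
#' for visual inspection in standard tree viewers.
#'
#' @param dend A [average_linkage()] dendrogram.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to a file.
#' @export
dend_newick <- function(dend, path = NULL) {
  h <- dend$height
  build <- function(node) {
    if (node < 0) return(list(str = dend$labels[-node], h = 0))
    kids <- lapply(dend$merge[node, ], build)
    parts <- vapply(kids, function(k) {
      sprintf("%s:%.10g", k$str, h[node] - k$h)
    }, character(1))
    list(str = sprintf("(%s)", paste(parts, collapse = ",")), h = h[node])
  }
  s <- paste0(build(nrow(dend$merge))$str, ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
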