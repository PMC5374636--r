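#' Expression matrix container
#'
#' An `expr_mat` holds a miRNA-by-sample matrix of expression intensities
#' (rows = miRNAs, columns = samples) together with a detection mask marking
#' which cells were detected on the platform. Undetected cells are `NA` in
#' `values` until [detection_filter()] imputes them. The intensity units are
#' whatever the platform produced; the pipeline never rescales them.
#'
#' @param values Numeric matrix with unique rownames (miRNA ids) and unique
#'   colnames (sample ids). `NA` cells are treated as undetected.
#' @param detection Optional logical matrix of the same shape; `FALSE` marks
#'   an undetected cell. Defaults to `!is.na(values)`. `values` must be `NA`
#'   only where `detection` is `FALSE`.
#'
#' @return An object of class `expr_mat`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("mir-", 1:3), c("s1", "s2")))
#' expr_mat(m)
#' @export
expr_mat <- function(values, detection = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs miRNA rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate miRNA ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  if (is.null(detection)) detection <- !is.na(values)
  detection <- as.matrix(detection)
  if (!identical(dim(detection), dim(values))) {
    stop("detection mask shape does not match values", call. = FALSE)
  }
  mode(detection) <- "logical"
  if (any(is.na(values) & detection)) {
    stop("NA expression value in a cell flagged as detected", call. = FALSE)
  }
  if (any(!is.finite(values[detection]))) {
    stop("non-finite expression value in a detected cell", call. = FALSE)
  }
  dimnames(detection) <- dimnames(values)
  structure(list(values = values, detection = detection), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d miRNAs x %d samples (%.1f%% detected)\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$detection)
  ))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' miRNA and sample identifiers of an expression matrix
#' @param x An [expr_mat()].
#' @return Character vector of ids.
#' @export
mirna_ids <- function(x) rownames(x$values)

#' @rdname mirna_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by miRNA id
#'
#' @param x An [expr_mat()].
#' @param ids miRNA ids to keep, in the order given.
#' @return A smaller `expr_mat`.
#' @export
expr_subset <- function(x, ids) {
  missing_ids <- setdiff(ids, mirna_ids(x))
  if (length(missing_ids) > 0) {
    stop("unknown miRNA ids: ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  expr_mat(x$values[ids, , drop = FALSE], x$detection[ids, , drop = FALSE])
}

#' Build an expression matrix from a tidy data frame
#'
#' The first column holds miRNA ids; every remaining column is one sample.
#' This is the in-memory twin of the TSV layout read by [read_expression()].
#'
#' @param df A data frame, first column miRNA id, other columns numeric.
#' @return An [expr_mat()].
#' @export
as_expr_mat <- function(df) {
  df <- as.data.frame(df)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  mode(vals) <- "double"
  rownames(vals) <- ids
  expr_mat(vals)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.expr_mat <- function(x, ...) {
  tibble::as_tibble(
    cbind(data.frame(mirna_id = mirna_ids(x), stringsAsFactors = FALSE),
          as.data.frame(x$values)),
    .name_repair = "minimal"
  )
}

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: a header row `id<TAB>sample1<TAB>...`, then one row per
#' miRNA with its id followed by numeric intensities. The token `NA` marks an
#' undetected cell. Ragged rows, duplicate ids and non-numeric tokens are
#' format errors.
#'
#' @param path Path to the TSV file.
#' @param transpose If `TRUE` the file is samples-by-miRNAs and is transposed
#'   on read.
#' @return An [expr_mat()].
#' @export
read_expression <- function(path, transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad) > 0) {
    stop("ragged row(s) in expression file at line(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  samples <- fields[[1]][-1]
  rows <- fields[-1]
  ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- vapply(rows, function(f) f[-1], character(ncol_expect - 1))
  body <- matrix(body, nrow = ncol_expect - 1) # columns = miRNAs here
  is_na <- body == "NA"
  vals <- suppressWarnings(as.numeric(body))
  if (any(is.na(vals) & !is_na)) {
    stop("non-numeric token in expression file", call. = FALSE)
  }
  m <- t(matrix(vals, nrow = ncol_expect - 1,
                dimnames = list(samples, ids)))
  if (transpose) {
    # file was samples x miRNAs: header names are miRNA ids, row ids samples
    m <- t(m)
  }
  expr_mat(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: undetected cells are written as `NA`,
#' values with full precision so a read-back round-trips.
#'
#' @param x An [expr_mat()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  vals <- x$values
  out <- matrix(format(vals, digits = 15, trim = TRUE, scientific = FALSE),
                nrow(vals), ncol(vals))
  out[!x$detection] <- "NA"
  lines <- c(
    paste(c("id", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], out[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and align two-class sample labels
#'
#' Two tab-separated columns: sample id, class token. The first distinct
#' class token encountered becomes class `c0` (the "positive" class for
#' sensitivity); the second becomes `c1`. Labels are reordered to match the
#' sample order of `expr`.
#'
#' @param path Path to the two-column TSV (no header).
#' @param expr The [expr_mat()] the labels must cover.
#' @return A tibble with columns `sample_id` and `class` (factor, levels
#'   `c(c0, c1)` in first-seen order).
#' @export
read_labels <- function(path, expr) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) != 2) stop("label file must have exactly two columns", call. = FALSE)
  sample_labels(df[[1]], df[[2]], expr)
}

#' Construct aligned sample labels
#'
#' @param ids Character vector of sample ids.
#' @param classes Class tokens aligned to `ids`; exactly two distinct tokens,
#'   each with at least two samples.
#' @param expr Optional [expr_mat()]; if given, `ids` must match its samples
#'   as a set and the result is reordered to the matrix's column order.
#' @return A tibble `sample_id`, `class`.
#' @export
sample_labels <- function(ids, classes, expr = NULL) {
  ids <- as.character(ids)
  classes <- as.character(classes)
  if (anyDuplicated(ids)) stop("duplicate sample id in labels", call. = FALSE)
  lv <- unique(classes) # first-seen order: lv[1] = c0
  if (length(lv) != 2) {
    stop("labels must contain exactly two classes, found ", length(lv), call. = FALSE)
  }
  if (min(table(classes)) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = ids, class = factor(classes, levels = lv))
  if (!is.null(expr)) {
    extra <- setdiff(ids, sample_ids(expr))
    absent <- setdiff(sample_ids(expr), ids)
    if (length(extra) || length(absent)) {
      stop("sample ids in labels and expression matrix differ: ",
           paste(c(extra, absent), collapse = ", "), call. = FALSE)
    }
    out <- out[match(sample_ids(expr), out$sample_id), ]
  }
  out
}

# Internal: labels tibble -> factor aligned to expr columns
align_classes <- function(labels, expr) {
  stopifnot(is.data.frame(labels), all(c("sample_id", "class") %in% names(labels)))
  idx <- match(sample_ids(expr), labels$sample_id)
  if (anyNA(idx)) stop("labels do not cover all samples", call. = FALSE)
  labels$class[idx]
}
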