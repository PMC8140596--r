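#' Two-class expression matrix
#'
#' The basic data container: a numeric samples-by-features matrix with a
#' binary class label per sample. Row names are sample identifiers, column
#' names are feature identifiers (gene symbols or miRNA names). Values are
#' expected to be expression measurements (non-negative normalized counts on
#' input; possibly standardized after normalization).
#'
#' @param values Numeric matrix, samples in rows (unique row names) and
#'   features in columns (unique column names).
#' @param classes Vector of class labels, one per row of `values`; exactly
#'   two distinct labels must be present.
#' @param positive The label of the case (positive) class. If `NULL`, it is
#'   guessed: a level matching a common case keyword ("pos", "case",
#'   "tumor", ...) if there is one, otherwise the minority class.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `classes` (factor) and `positive`.
#' @export
expression_matrix <- function(values, classes, positive = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("input-format error: 'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("input-format error: 'values' needs sample row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("data error: duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("data error: duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  classes <- droplevels(as.factor(classes))
  if (length(classes) != nrow(values))
    stop("data error: one class label per sample required (",
         length(classes), " labels for ", nrow(values), " samples)")
  if (nlevels(classes) != 2L)
    stop("data error: exactly two class labels required, found: ",
         paste(levels(classes), collapse = ", "))
  positive <- match_positive(classes, positive)
  structure(list(values = values, classes = classes, positive = positive),
            class = "ExpressionMatrix")
}

match_positive <- function(classes, positive) {
  lev <- levels(classes)
  if (!is.null(positive)) {
    if (!positive %in% lev)
      stop("data error: positive label '", positive,
           "' is not one of the class labels (", paste(lev, collapse = ", "), ")")
    return(positive)
  }
  keywords <- c("pos", "positive", "case", "tumor", "tumour", "cancer",
                "disease", "1", "yes", "true")
  hit <- lev[tolower(lev) %in% keywords]
  if (length(hit) == 1L) return(hit)
  counts <- table(classes)
  lev[which.min(counts)]  # minority class; first level on ties
}

# Internal subset that preserves structure (keeps both factor levels).
em_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  cl <- x$classes
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(v)) else samples
    if (anyNA(idx)) stop("data error: unknown sample id(s)")
    v <- v[idx, , drop = FALSE]
    cl <- cl[idx]
  }
  if (!is.null(features)) {
    fdx <- if (is.character(features)) match(features, colnames(v)) else features
    if (anyNA(fdx)) stop("data error: unknown feature id(s)")
    v <- v[, fdx, drop = FALSE]
  }
  structure(list(values = v, classes = cl, positive = x$positive),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(x$classes)
  cat("ExpressionMatrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n  classes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      " (positive: ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
class_labels <- function(x) x$classes

#' Read a sample-by-feature expression table
#'
#' Reads a delimited text file (comma or tab, auto-detected) with one header
#' row, a sample-identifier column, a two-level class column, and numeric
#' expression columns. By default the first column is the identifier and the
#' second the class, matching the conventional input layout. Non-numeric
#' cells in expression columns are recorded as missing (`NA`), never as
#' zero.
#'
#' @param path Path to the file.
#' @param id_column,class_column Column names; `NULL` means positional
#'   (first and second column respectively).
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, id_column = NULL, class_column = NULL,
                                  positive = NULL) {
  if (!file.exists(path))
    stop("input-format error: file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("input-format error: empty file: ", path)
  sep <- detect_sep(first)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = "character")
  if (nrow(df) == 0L)
    stop("input-format error: no data rows in ", path)
  pick <- function(col, default_idx, what) {
    if (is.null(col)) return(default_idx)
    j <- match(col, names(df))
    if (is.na(j))
      stop("input-format error: ", what, " column '", col, "' not found in ", path)
    j
  }
  id_j <- pick(id_column, 1L, "sample-identifier")
  cl_j <- pick(class_column, 2L, "class")
  ids <- as.character(df[[id_j]])
  if (anyDuplicated(ids))
    stop("data error: duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  classes <- as.character(df[[cl_j]])
  tab <- table(classes)
  if (length(tab) != 2L)
    stop("data error: exactly two class labels required in ", path,
         ", found: ", paste(names(tab), collapse = ", "))
  if (any(tab < 2L))
    stop("data error: fewer than 2 samples in class '",
         names(tab)[which.min(tab)], "' in ", path)
  feat <- setdiff(seq_along(df), c(id_j, cl_j))
  if (length(feat) == 0L)
    stop("input-format error: no expression columns in ", path)
  vals <- suppressWarnings(
    vapply(df[feat], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(ids, names(df)[feat])
  expression_matrix(vals, classes, positive = positive)
}

#' Write an expression matrix as delimited text
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file.
#' @param id_column,class_column Header names for the two leading columns.
#' @param sep Field separator.
#' @export
write_expression_table <- function(x, path, id_column = "Case ID",
                                   class_column = "Class", sep = ",") {
  df <- data.frame(id = rownames(x$values),
                   class = as.character(x$classes),
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c(id_column, class_column)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a gene and a miRNA expression matrix over shared samples
#'
#' Restricts both matrices to the intersection of their sample identifiers,
#' in a common order, and verifies that the class label of every shared
#' sample agrees between the two files.
#'
#' @param genes,mirna `ExpressionMatrix` objects over overlapping samples.
#' @return A `PairedDataset`: list with elements `genes` and `mirna`, both
#'   over identical samples in identical order.
#' @export
align_pair <- function(genes, mirna) {
  stopifnot(inherits(genes, "ExpressionMatrix"), inherits(mirna, "ExpressionMatrix"))
  shared <- intersect(sample_ids(genes), sample_ids(mirna))
  if (length(shared) == 0L)
    stop("data error: no samples shared between the gene and miRNA tables")
  gcl <- as.character(genes$classes)[match(shared, sample_ids(genes))]
  mcl <- as.character(mirna$classes)[match(shared, sample_ids(mirna))]
  bad <- shared[gcl != mcl]
  if (length(bad) > 0L)
    stop("data error: conflicting class labels for sample(s): ",
         paste(bad, collapse = ", "))
  g <- em_subset(genes, samples = shared)
  m <- em_subset(mirna, samples = shared)
  g$classes <- droplevels(g$classes)
  m$classes <- droplevels(m$classes)
  if (nlevels(g$classes) != 2L)
    stop("data error: fewer than two classes remain after alignment")
  m$positive <- g$positive
  structure(list(genes = g, mirna = m), class = "PairedDataset")
}

#' @export
print.PairedDataset <- function(x, ...) {
  cat("PairedDataset over", nrow(x$genes$values), "samples:\n  genes: ",
      ncol(x$genes$values), " features\n  miRNA: ",
      ncol(x$mirna$values), " features\n")
  invisible(x)
}

# Subset both halves of a pair to the given sample ids (same order).
pair_subset_samples <- function(pair, ids) {
  structure(list(genes = em_subset(pair$genes, samples = ids),
                 mirna = em_subset(pair$mirna, samples = ids)),
            class = "PairedDataset")
}
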