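# Correlation step (C) and grouping step (G): Pearson miRNA-by-gene
# correlations and per-miRNA target-gene groups below the anti-correlation
# threshold.

#' Pearson correlation with explicit degenerate-input handling
#'
#' Standard product-moment correlation of two equal-length vectors. A
#' constant vector has no defined correlation; `NA` is returned so callers
#' can treat the pair as a non-association.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient, or `NA` if either vector is constant.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("data error: vectors of unequal length")
  if (length(x) < 3L)
    stop("data error: at least 3 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' miRNA-by-gene Pearson correlation matrix
#'
#' Correlates every miRNA profile with every gene profile across the shared
#' samples of a paired dataset. Undefined entries (constant profiles) are
#' recorded as `NA`, which downstream grouping treats as no association.
#'
#' @param pair A `PairedDataset` (preprocessed).
#' @return A numeric matrix, miRNAs in rows, genes in columns, entries in
#'   \[-1, 1\] or `NA`.
#' @export
correlation_matrix <- function(pair) {
  stopifnot(inherits(pair, "PairedDataset"))
  suppressWarnings(stats::cor(pair$mirna$values, pair$genes$values))
}

#' Form per-miRNA target-gene groups from a correlation matrix
#'
#' The group of a miRNA is the set of genes whose correlation with it is at
#' or below `threshold` (anti-correlation; the default -0.6 is a stringent
#' cutoff for high-confidence associations). miRNAs with empty groups are
#' omitted; a gene may belong to several groups.
#'
#' @param corr miRNA-by-gene correlation matrix as from
#'   [correlation_matrix()].
#' @param threshold Inclusive correlation cutoff, strictly between -1 and 0.
#' @return A named list mapping miRNA id to character vector of gene ids
#'   (class `TargetGeneGroups`), in miRNA input order.
#' @export
build_groups <- function(corr, threshold = -0.6) {
  stopifnot(is.matrix(corr))
  if (!is.numeric(threshold) || threshold <= -1 || threshold >= 0)
    stop("parameter error: threshold must lie strictly between -1 and 0")
  genes <- colnames(corr)
  groups <- apply(corr, 1L, function(r) genes[!is.na(r) & r <= threshold],
                  simplify = FALSE)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) == 0L)
    stop("pipeline error: no miRNA-mRNA associations at threshold ", threshold)
  structure(groups, class = "TargetGeneGroups")
}

#' @export
print.TargetGeneGroups <- function(x, ...) {
  cat("TargetGeneGroups:", length(x), "miRNA group(s), ",
      "group sizes ", paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Export target-gene groups as two-column delimited text
#'
#' One row per miRNA: the miRNA id and its comma-joined gene list.
#'
#' @param groups A `TargetGeneGroups` object.
#' @param path Output file.
#' @param sep Field separator between the two columns.
#' @export
write_target_groups <- function(groups, path, sep = "\t") {
  df <- data.frame(miRNA = names(groups),
                   Targets = vapply(groups, paste, "", collapse = ", "),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
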