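# Group ranking (R): score each miRNA group by repeated stratified hold-out
# classification restricted to its genes, then sort groups by accuracy.

#' Restrict a gene expression matrix to one group's genes
#'
#' Column subset keeping class labels and sample order. Group genes absent
#' from the matrix are ignored with a warning; `NULL` is returned when no
#' group gene is present so callers can skip the group.
#'
#' @param genes An `ExpressionMatrix` of gene expression.
#' @param group Character vector of gene ids.
#' @export
make_sub_data <- function(genes, group) {
  stopifnot(inherits(genes, "ExpressionMatrix"))
  present <- intersect(group, feature_ids(genes))
  if (length(present) == 0L) {
    warning("no group gene present in the expression matrix; group skipped")
    return(NULL)
  }
  if (length(present) < length(group))
    warning(length(group) - length(present), " group gene(s) absent from the matrix")
  em_subset(genes, features = present)
}

#' Score one gene group by repeated stratified hold-out classification
#'
#' Performs `r` independent stratified splits at train fraction `f`
#' (80:20 by default), trains the classifier on each training part
#' restricted to the group's genes, predicts the held-out part, and pools
#' the confusion counts over the repeats (micro-average, robust for tiny
#' test folds; `aggregate = "macro"` averages per-repeat metrics instead).
#' Deterministic given `seed`.
#'
#' @param sub_data An `ExpressionMatrix` already restricted to the group's
#'   genes, with at least 2 samples per class.
#' @param r Number of repeats.
#' @param f Train fraction of each split.
#' @param classifier `"random_forest"` (default) or `"svm"`.
#' @param seed Integer seed.
#' @param aggregate Confusion-count pooling (`"micro"`) or per-repeat metric
#'   averaging (`"macro"`).
#' @return A [compute_metrics()] `metric_set` (for `"macro"`, metric fields
#'   are repeat averages and counts are totals).
#' @export
score_group <- function(sub_data, r = 5L, f = 0.8,
                        classifier = c("random_forest", "svm"), seed = 1L,
                        aggregate = c("micro", "macro")) {
  stopifnot(inherits(sub_data, "ExpressionMatrix"))
  classifier <- match.arg(classifier)
  aggregate <- match.arg(aggregate)
  positive <- sub_data$positive
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  per_repeat <- vector("list", r)
  for (rep_i in seq_len(r)) {
    rep_seed <- derive_seed(seed, rep_i)
    split <- stratified_split(sub_data, train_fraction = f, seed = rep_seed)
    fit <- with_seed(derive_seed(rep_seed, "fit"),
                     fit_classifier(split$train$values, split$train$classes,
                                    classifier))
    pred <- predict_classifier(fit, split$test$values, positive)
    cc <- confusion_counts(pred$class, split$test$classes, positive)
    counts <- counts + cc
    per_repeat[[rep_i]] <- cc
  }
  if (aggregate == "micro")
    return(compute_metrics(counts["tp"], counts["fp"], counts["tn"], counts["fn"]))
  reps <- lapply(per_repeat, function(cc)
    compute_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"]))
  out <- compute_metrics(counts["tp"], counts["fp"], counts["tn"], counts["fn"])
  for (field in c("accuracy", "sensitivity", "specificity", "recall",
                  "precision", "f_measure", "cohens_kappa"))
    out[[field]] <- mean(vapply(reps, `[[`, numeric(1), field))
  out
}

#' Rank all miRNA groups by cross-validated classification accuracy
#'
#' Scores every group with [score_group()] and returns the table sorted in
#' decreasing accuracy. Every group's scoring seed is derived from `seed`
#' and the miRNA identifier, so the ranking is invariant to group insertion
#' order. Ties are broken by higher F-measure, then larger group, then
#' lexicographic miRNA id.
#'
#' @param genes Gene `ExpressionMatrix` (training data).
#' @param groups A `TargetGeneGroups` mapping.
#' @inheritParams score_group
#' @return A `GroupScoreTable` data frame with columns `Group`, `Accuracy`,
#'   `Sensitivity`, `Specificity`, `Recall`, `Precision`, `F-measure`,
#'   `Cohen's kappa` and `#Genes`, plus a `genes` attribute carrying each
#'   group's gene list.
#' @export
rank_groups <- function(genes, groups, r = 5L, f = 0.8,
                        classifier = c("random_forest", "svm"), seed = 1L,
                        aggregate = c("micro", "macro")) {
  stopifnot(inherits(genes, "ExpressionMatrix"))
  classifier <- match.arg(classifier)
  aggregate <- match.arg(aggregate)
  rows <- list()
  kept_genes <- list()
  for (mirna in names(groups)) {
    sub <- make_sub_data(genes, groups[[mirna]])
    if (is.null(sub)) next
    ms <- score_group(sub, r = r, f = f, classifier = classifier,
                      seed = derive_seed(seed, mirna), aggregate = aggregate)
    rows[[mirna]] <- data.frame(
      Group = mirna, Accuracy = ms$accuracy, Sensitivity = ms$sensitivity,
      Specificity = ms$specificity, Recall = ms$recall,
      Precision = ms$precision, `F-measure` = ms$f_measure,
      `Cohen's kappa` = ms$cohens_kappa,
      `#Genes` = ncol(sub$values),
      check.names = FALSE, stringsAsFactors = FALSE)
    kept_genes[[mirna]] <- feature_ids(sub)
  }
  if (length(rows) == 0L)
    stop("pipeline error: no scoreable group")
  tab <- do.call(rbind, rows)
  ord <- order(-tab$Accuracy, -tab$`F-measure`, -tab$`#Genes`, tab$Group)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, genes = kept_genes, class = c("GroupScoreTable", "data.frame"))
}

#' Write a group score table with its canonical column names
#'
#' @param table A `GroupScoreTable`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_score_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
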