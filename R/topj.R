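# Cumulative top-j models: the union of the genes of the j best-ranked
# groups, fit on training data and evaluated on held-out test data.

#' Genes of the top-j ranked groups
#'
#' Deduplicated union of the gene lists of the `j` best-ranked groups, in
#' first-appearance order. `j` beyond the number of ranked groups is
#' clamped with a warning.
#'
#' @param table A `GroupScoreTable` from [rank_groups()].
#' @param groups The `TargetGeneGroups` the table was built from.
#' @param j Cumulative depth (>= 1).
#' @return Character vector of gene ids.
#' @export
genes_of_top_j <- function(table, groups, j) {
  stopifnot(inherits(table, "GroupScoreTable"), j >= 1L)
  if (j > nrow(table)) {
    warning("j = ", j, " exceeds the ", nrow(table),
            " ranked group(s); clamped")
    j <- nrow(table)
  }
  top <- table$Group[seq_len(j)]
  unique(unlist(groups[top], use.names = FALSE))
}

#' Fit a classifier on a gene list and evaluate it on held-out data
#'
#' Trains on the training matrix restricted to `gene_list` and computes the
#' full metric set plus AUC on the test matrix. The test matrix must be
#' untouched by every upstream training-side step (differential-expression
#' filtering, correlation, grouping, ranking). Genes absent from either
#' matrix are dropped with a warning. Deterministic given `seed`.
#'
#' @param train,test Gene `ExpressionMatrix` objects sharing a feature
#'   namespace, over disjoint samples.
#' @param gene_list Non-empty character vector of gene ids.
#' @param classifier `"random_forest"` or `"svm"`.
#' @param seed Integer seed.
#' @return List with `gene_count`, `metrics` (a `metric_set`) and `auc`.
#' @export
fit_and_eval <- function(train, test, gene_list,
                         classifier = c("random_forest", "svm"), seed = 1L) {
  stopifnot(inherits(train, "ExpressionMatrix"),
            inherits(test, "ExpressionMatrix"))
  classifier <- match.arg(classifier)
  if (length(gene_list) == 0L)
    stop("data error: empty gene list")
  usable <- intersect(intersect(gene_list, feature_ids(train)),
                      feature_ids(test))
  if (length(usable) == 0L)
    stop("data error: none of the listed genes present in both matrices")
  if (length(usable) < length(gene_list))
    warning(length(gene_list) - length(usable),
            " gene(s) absent from train or test matrix; dropped")
  positive <- train$positive
  tr <- em_subset(train, features = usable)
  te <- em_subset(test, features = usable)
  fit <- with_seed(seed, fit_classifier(tr$values, tr$classes, classifier))
  pred <- predict_classifier(fit, te$values, positive)
  cc <- confusion_counts(pred$class, te$classes, positive)
  list(gene_count = length(usable),
       metrics = compute_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"]),
       auc = auc_score(pred$score, te$classes, positive))
}
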