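# Internal classifier wrapper. Two fixed models are exposed throughout the
# package: a random forest (default; 100 trees, default mtry/depth) and a
# linear-kernel SVM. Hyperparameters are fixed: group scoring compares
# feature sets, not tuned models.

fit_classifier <- function(x, y, classifier = c("random_forest", "svm")) {
  classifier <- match.arg(classifier)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L)
    stop("data error: classifier training requires both classes present")
  model <- switch(classifier,
    random_forest = randomForest::randomForest(x = x, y = y, ntree = 100L),
    svm = e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE))
  structure(list(model = model, classifier = classifier, levels = levels(y)),
            class = "mirank_classifier")
}

# Predict class labels and a positive-class score for new samples.
# For the forest the score is the out-of-bag-style class probability; for
# the SVM the signed decision value oriented toward the positive class
# (rank-equivalent to a probability for AUC purposes).
predict_classifier <- function(fit, newx, positive) {
  if (fit$classifier == "random_forest") {
    cls <- stats::predict(fit$model, newx, type = "response")
    prob <- stats::predict(fit$model, newx, type = "prob")
    score <- prob[, positive]
  } else {
    cls <- stats::predict(fit$model, newx, decision.values = TRUE)
    dv <- attr(cls, "decision.values")
    lab <- colnames(dv)[1L]  # "A/B": positive decision favours class A
    score <- if (startsWith(lab, paste0(positive, "/"))) dv[, 1L] else -dv[, 1L]
  }
  list(class = factor(as.character(cls), levels = fit$levels), score = score)
}

# Accumulate a confusion table of predictions against truth.
confusion_counts <- function(predicted, truth, positive) {
  pred_pos <- as.character(predicted) == positive
  true_pos <- as.character(truth) == positive
  c(tp = sum(pred_pos & true_pos), fp = sum(pred_pos & !true_pos),
    tn = sum(!pred_pos & !true_pos), fn = sum(!pred_pos & true_pos))
}
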