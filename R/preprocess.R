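# Preprocessing: missing-value removal, normalization, prevalence filter,
# differential-expression filter. Fixed pipeline order:
# remove_missing -> (optional prevalence_filter) -> normalize -> de_filter.

#' Drop features containing missing values
#'
#' Removes every feature column with at least one missing cell; the sample
#' set is unchanged. Features, not samples, are dropped because samples are
#' the scarce resource in case/control designs.
#'
#' @param x An `ExpressionMatrix`.
#' @return The filtered `ExpressionMatrix`.
#' @export
remove_missing <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  bad <- colSums(is.na(x$values)) > 0L
  if (all(bad))
    stop("data error: every feature contains missing values")
  if (any(bad))
    warning(sum(bad), " feature(s) dropped for missing values")
  em_subset(x, features = which(!bad))
}

#' Normalize an expression matrix
#'
#' `log2p1_zscore` (the default for raw normalized-count input) applies
#' `log2(x + 1)` and then standardizes every feature to mean 0 / sd 1;
#' `zscore` standardizes only (appropriate when values are already on a
#' log-like scale); `none` is the identity. Constant features cannot be
#' standardized and are dropped with a warning.
#'
#' @param x An `ExpressionMatrix` with no missing values.
#' @param method One of `"log2p1_zscore"`, `"zscore"`, `"none"`.
#' @export
normalize_expression <- function(x, method = c("log2p1_zscore", "zscore", "none")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  if (anyNA(x$values))
    stop("data error: missing values present; run remove_missing() first")
  if (method == "none") return(x)
  v <- x$values
  if (method == "log2p1_zscore") {
    if (any(v < 0))
      stop("data error: negative values under log2(x+1); use method='zscore' or 'none'")
    v <- log2(v + 1)
  }
  sds <- apply(v, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (all(const))
    stop("data error: all features constant; nothing to standardize")
  if (any(const))
    warning(sum(const), " constant feature(s) dropped during standardization")
  v <- v[, !const, drop = FALSE]
  v <- scale(v)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  out <- x
  out$values <- v
  out
}

#' Prevalence filter on raw-scale expression
#'
#' Keeps features whose value is at least `min_value` in at least
#' `min_fraction` of the samples (both bounds inclusive). Intended for
#' raw-scale (pre-normalization) values; the conventional cutoff keeps
#' features with normalized expression >= 1 in >= 50% of samples.
#'
#' @param x An `ExpressionMatrix`.
#' @param min_value Expression cutoff (default 1).
#' @param min_fraction Required fraction of samples (default 0.5).
#' @export
prevalence_filter <- function(x, min_value = 1, min_fraction = 0.5) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  frac <- colMeans(x$values >= min_value, na.rm = TRUE)
  em_subset(x, features = which(frac >= min_fraction))
}

# Vectorized two-sample t-test over feature columns. Returns the two-sided
# p-value per feature; NaN where the statistic is undefined (both classes
# constant with equal means).
ttest_pvalues <- function(values, classes, var_equal = FALSE) {
  lev <- levels(classes)
  a <- values[classes == lev[1L], , drop = FALSE]
  b <- values[classes == lev[2L], , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(b, 2L, m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  # zero variance in both classes: infinite separation if the means differ,
  # undefined otherwise
  degenerate <- se == 0
  p[degenerate & m1 != m2] <- 0
  p[degenerate & m1 == m2] <- NaN
  p
}

#' Differential-expression filter by two-sample t-test
#'
#' Tests every feature for a mean difference between the two classes and
#' retains features with p-value at or below `alpha`. Welch's unequal
#' variance form is the default; the pooled-variance form is available via
#' `var_equal = TRUE`. Features whose statistic is undefined (constant in
#' both classes with equal means) are dropped with a warning. The p-values
#' of the retained features are attached as attribute `"de_p_values"`.
#'
#' @param x An `ExpressionMatrix` with at least 2 samples per class.
#' @param alpha Significance cutoff, inclusive (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch's.
#' @export
de_filter_ttest <- function(x, alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- table(x$classes)
  if (any(tab < 2L))
    stop("data error: at least 2 samples per class required for the t-test")
  p <- ttest_pvalues(x$values, x$classes, var_equal = var_equal)
  names(p) <- feature_ids(x)
  undef <- is.nan(p)
  if (any(undef))
    warning(sum(undef), " feature(s) with undefined t statistic dropped")
  keep <- !undef & p <= alpha
  out <- em_subset(x, features = which(keep))
  attr(out, "de_p_values") <- p[keep]
  out
}
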