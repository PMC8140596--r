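# Outer Monte-Carlo cross-validation driver: under-sampling, stratified
# splitting, and the per-iteration grouping -> ranking -> top-j chain.

#' Majority-class under-sampling
#'
#' Keeps the minority class whole and down-samples the majority class
#' without replacement to at most `ratio` times the minority count (the
#' conventional 1:2 setting by default). Deterministic given `seed`.
#'
#' @param x An `ExpressionMatrix` with two classes present.
#' @param ratio Maximum majority:minority ratio (>= 1).
#' @param seed Integer seed.
#' @export
undersample <- function(x, ratio = 2, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ratio < 1) stop("parameter error: undersample ratio must be >= 1")
  keep <- undersample_ids(sample_ids(x), x$classes, ratio, seed)
  em_subset(x, samples = keep)
}

# Shared id-level implementation so paired matrices stay in lockstep.
undersample_ids <- function(ids, classes, ratio, seed) {
  tab <- table(classes)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  n_keep <- min(tab[[majority]], floor(ratio * tab[[minority]]))
  maj_ids <- ids[classes == majority]
  kept_maj <- if (n_keep < length(maj_ids)) {
    with_seed(seed, sample(maj_ids, n_keep))
  } else maj_ids
  ids[ids %in% c(ids[classes == minority], kept_maj)]
}

#' Stratified train/test split
#'
#' Allocates `floor(train_fraction * n_c)` samples of every class to the
#' training part (clamped so both parts retain at least one sample per
#' class) and the remainder to the test part. The two parts are disjoint
#' and exhaustive. Deterministic given `seed`.
#'
#' @param x An `ExpressionMatrix` with at least 2 samples per class.
#' @param train_fraction Proportion assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` `ExpressionMatrix` objects.
#' @export
stratified_split <- function(x, train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("parameter error: train_fraction must lie in (0, 1)")
  tab <- table(x$classes)
  if (any(tab < 2L))
    stop("data error: class '", names(tab)[which.min(tab)],
         "' too small to appear in both train and test")
  ids <- sample_ids(x)
  train_ids <- character()
  with_seed(seed, {
    for (lev in levels(x$classes)) {
      cls_ids <- ids[x$classes == lev]
      n_train <- min(max(floor(train_fraction * length(cls_ids)), 1L),
                     length(cls_ids) - 1L)
      train_ids <- c(train_ids, sample(cls_ids, n_train))
    }
  })
  test_ids <- setdiff(ids, train_ids)
  list(train = em_subset(x, samples = ids[ids %in% train_ids]),
       test = em_subset(x, samples = test_ids))
}

#' Monte-Carlo cross-validation configuration
#'
#' Bundles every tunable of the outer loop with its conventional default:
#' 100 iterations of a 90/10 stratified split with 1:2 under-sampling,
#' correlation threshold -0.6, differential-expression alpha 0.05, internal
#' group scoring with r = 5 repeats of an 80:20 split, and cumulative
#' models down to depth j = 10.
#'
#' @param n_iterations Number of outer Monte-Carlo iterations.
#' @param train_fraction Outer train proportion.
#' @param undersample_ratio Majority:minority cap (>= 1).
#' @param undersample_scope `"all"` applies under-sampling before the
#'   split; `"train_only"` leaves the test part untouched.
#' @param master_seed Seed from which all per-iteration seeds derive.
#' @param j_max Maximum cumulative top-group depth.
#' @param classifier `"random_forest"` or `"svm"`.
#' @param cor_threshold Grouping threshold (inclusive, negative).
#' @param alpha Differential-expression cutoff.
#' @param r Internal scoring repeats.
#' @param f Internal scoring train fraction.
#' @param max_empty_fraction Abort when more than this fraction of
#'   iterations yields no group.
#' @export
mccv_config <- function(n_iterations = 100L, train_fraction = 0.9,
                        undersample_ratio = 2, undersample_scope = c("all", "train_only"),
                        master_seed = 1L, j_max = 10L,
                        classifier = c("random_forest", "svm"),
                        cor_threshold = -0.6, alpha = 0.05,
                        r = 5L, f = 0.8, max_empty_fraction = 0.5) {
  stopifnot(n_iterations >= 1L, train_fraction > 0, train_fraction < 1,
            undersample_ratio >= 1, j_max >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 undersample_ratio = undersample_ratio,
                 undersample_scope = match.arg(undersample_scope),
                 master_seed = as.integer(master_seed),
                 j_max = as.integer(j_max),
                 classifier = match.arg(classifier),
                 cor_threshold = cor_threshold, alpha = alpha,
                 r = as.integer(r), f = f,
                 max_empty_fraction = max_empty_fraction),
            class = "mccv_config")
}

#' Run the full Monte-Carlo cross-validation loop
#'
#' For every iteration a seed is derived from the master seed, the paired
#' dataset is under-sampled and split into stratified train/test parts, and
#' the entire training-side chain runs on the training part only:
#' differential-expression filtering of genes and miRNAs, the miRNA-by-gene
#' correlation matrix, target-gene grouping, and group ranking by internal
#' cross-validated classification. Cumulative top-j models (j = 1 ..
#' `j_max`) are then fit on the training part and evaluated on the held-out
#' test part. Per iteration the miRNA ranking, the inherited-rank gene
#' ranking (every gene takes the rank of its miRNA group, deduplicated at
#' its best rank), the group score table, the top-j performance and the
#' sample ids of both parts are recorded.
#'
#' Iterations in which no miRNA-gene association passes the correlation
#' threshold are recorded as empty; the run aborts only when more than
#' `max_empty_fraction` of iterations are empty.
#'
#' @param pair A preprocessed `PairedDataset` (aligned, missing values
#'   removed, normalized).
#' @param config An [mccv_config()].
#' @return An object of class `mccv_result`: list of per-iteration records
#'   with the configuration and feature universes attached as attributes.
#' @export
run_mccv <- function(pair, config = mccv_config()) {
  stopifnot(inherits(pair, "PairedDataset"), inherits(config, "mccv_config"))
  records <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    records[[i]] <- run_mccv_iteration(pair, config, i)
  }
  n_empty <- sum(vapply(records, function(r) r$empty, logical(1)))
  if (n_empty > config$max_empty_fraction * config$n_iterations)
    stop("pipeline error: ", n_empty, " of ", config$n_iterations,
         " iterations produced no miRNA-mRNA groups")
  structure(records,
            class = "mccv_result",
            config = config,
            mirna_universe = feature_ids(pair$mirna),
            gene_universe = feature_ids(pair$genes))
}

run_mccv_iteration <- function(pair, config, i) {
  seed <- derive_seed(config$master_seed, i)
  empty_record <- function(train_ids, test_ids) {
    list(iteration = i, seed = seed, empty = TRUE,
         train_ids = train_ids, test_ids = test_ids,
         mirna_ranking = numeric(), gene_ranking = numeric(),
         score_table = NULL, topj = NULL, groups = NULL)
  }

  ids <- sample_ids(pair$genes)
  if (config$undersample_scope == "all") {
    keep <- undersample_ids(ids, pair$genes$classes, config$undersample_ratio,
                            derive_seed(seed, "undersample"))
    pair_i <- pair_subset_samples(pair, keep)
  } else {
    pair_i <- pair
  }
  split <- stratified_split(pair_i$genes, config$train_fraction,
                            derive_seed(seed, "split"))
  train_ids <- sample_ids(split$train)
  test_ids <- sample_ids(split$test)
  if (config$undersample_scope == "train_only") {
    train_ids <- undersample_ids(train_ids,
                                 pair_i$genes$classes[match(train_ids, ids)],
                                 config$undersample_ratio,
                                 derive_seed(seed, "undersample"))
  }
  train <- pair_subset_samples(pair_i, train_ids)
  test <- pair_subset_samples(pair_i, test_ids)

  # training-side chain: DE filter -> correlation -> groups -> ranking
  de_genes <- tryCatch(
    suppressWarnings(de_filter_ttest(train$genes, alpha = config$alpha)),
    error = function(e) NULL)
  de_mirna <- tryCatch(
    suppressWarnings(de_filter_ttest(train$mirna, alpha = config$alpha)),
    error = function(e) NULL)
  if (is.null(de_genes) || is.null(de_mirna) ||
      ncol(de_genes$values) == 0L || ncol(de_mirna$values) == 0L) {
    warning("iteration ", i, ": no features pass the DE filter")
    return(empty_record(train_ids, test_ids))
  }
  train_de <- structure(list(genes = de_genes, mirna = de_mirna),
                        class = "PairedDataset")
  corr <- correlation_matrix(train_de)
  groups <- tryCatch(build_groups(corr, config$cor_threshold),
                     error = function(e) NULL)
  if (is.null(groups)) {
    warning("iteration ", i, ": no groups at threshold ", config$cor_threshold)
    return(empty_record(train_ids, test_ids))
  }
  score_table <- suppressWarnings(
    rank_groups(de_genes, groups, r = config$r, f = config$f,
                classifier = config$classifier,
                seed = derive_seed(seed, "rank")))

  # cumulative top-j models, trained on train, evaluated on held-out test
  n_groups <- nrow(score_table)
  js <- seq_len(min(config$j_max, n_groups))
  topj <- lapply(js, function(j) {
    gl <- genes_of_top_j(score_table, groups, j)
    res <- suppressWarnings(
      fit_and_eval(train$genes, test$genes, gl,
                   classifier = config$classifier,
                   seed = derive_seed(seed, "topj", j)))
    data.frame(j = j, n_genes = res$gene_count,
               accuracy = res$metrics$accuracy,
               sensitivity = res$metrics$sensitivity,
               specificity = res$metrics$specificity,
               auc = res$auc)
  })
  topj <- do.call(rbind, topj)

  mirna_ranking <- stats::setNames(seq_len(n_groups), score_table$Group)
  gene_ranking <- numeric()
  for (k in seq_len(n_groups)) {
    g_new <- setdiff(groups[[score_table$Group[k]]], names(gene_ranking))
    gene_ranking[g_new] <- k
  }

  list(iteration = i, seed = seed, empty = FALSE,
       train_ids = train_ids, test_ids = test_ids,
       mirna_ranking = mirna_ranking, gene_ranking = gene_ranking,
       score_table = score_table, topj = topj,
       groups = unclass(groups))
}

#' @export
print.mccv_result <- function(x, ...) {
  n_empty <- sum(vapply(x, function(r) r$empty, logical(1)))
  cat("mccv_result:", length(x), "iteration(s),", n_empty, "empty\n")
  invisible(x)
}

#' Per-depth performance summary across iterations
#'
#' Mean and standard deviation of accuracy, sensitivity, specificity and
#' AUC, plus the mean distinct-gene count, for every cumulative depth j
#' across the non-empty iterations.
#'
#' @param result An `mccv_result`.
#' @return A data frame with one row per depth j.
#' @export
summarize_performance <- function(result) {
  stopifnot(inherits(result, "mccv_result"))
  topj <- do.call(rbind, lapply(result, function(r) r$topj))
  if (is.null(topj) || nrow(topj) == 0L)
    return(data.frame(j = integer(), n_genes = numeric(),
                      accuracy = numeric(), accuracy_sd = numeric(),
                      sensitivity = numeric(), sensitivity_sd = numeric(),
                      specificity = numeric(), specificity_sd = numeric(),
                      auc = numeric(), auc_sd = numeric()))
  out <- lapply(split(topj, topj$j), function(d) {
    data.frame(j = d$j[1L], n_genes = mean(d$n_genes),
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               sensitivity = mean(d$sensitivity),
               sensitivity_sd = stats::sd(d$sensitivity),
               specificity = mean(d$specificity),
               specificity_sd = stats::sd(d$specificity),
               auc = mean(d$auc, na.rm = TRUE),
               auc_sd = stats::sd(d$auc, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$j), , drop = FALSE]
}
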