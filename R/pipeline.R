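# End-to-end pipeline: read/preprocess paired tables, run the Monte-Carlo
# loop, aggregate, and write the three output files plus the resolved
# configuration.

#' Run the full integration pipeline
#'
#' Executes the complete workflow: read (or accept) the paired expression
#' tables, align samples, drop features with missing values, optionally
#' apply the prevalence filter on the raw scale, normalize, run the
#' Monte-Carlo cross-validation loop (under-sampling, stratified split,
#' differential-expression filter, correlation grouping, group ranking and
#' cumulative top-j evaluation per iteration), and aggregate the
#' per-iteration rankings. Three output files are written to `output_dir`:
#' `mirna_ranking.tsv` (miRNA, aggregated p-value score, targets, gene
#' count), `gene_ranking.tsv` (gene, aggregated p-value score, supporting
#' miRNAs) and `performance.tsv` (per-depth mean and sd of accuracy,
#' sensitivity, specificity and AUC across iterations), plus
#' `association_scores.tsv` and the resolved configuration `config.yaml`.
#' Re-running with the written configuration reproduces the outputs
#' bit-identically.
#'
#' @param genes_file,mirna_file Paths to the delimited expression tables
#'   (ignored when `pair` is given).
#' @param pair Optionally, an already-aligned `PairedDataset`.
#' @param output_dir Output directory, created if missing; `NULL` skips
#'   file output.
#' @param config An [mccv_config()].
#' @param normalization Passed to [normalize_expression()].
#' @param prevalence Apply [prevalence_filter()] before normalization.
#' @param positive Case-class label (guessed when `NULL`).
#' @param id_column,class_column Column names in the input files (`NULL`
#'   for positional).
#' @return Invisibly, a list with the `mccv_result`, the three aggregated
#'   tables and the performance summary.
#' @export
run_pipeline <- function(genes_file = NULL, mirna_file = NULL, pair = NULL,
                         output_dir = NULL, config = mccv_config(),
                         normalization = "log2p1_zscore", prevalence = FALSE,
                         positive = NULL, id_column = NULL, class_column = NULL) {
  if (is.null(pair)) {
    if (is.null(genes_file) || is.null(mirna_file))
      stop("input-format error: supply either 'pair' or both input files")
    genes <- read_expression_table(genes_file, id_column, class_column, positive)
    mirna <- read_expression_table(mirna_file, id_column, class_column, positive)
    pair <- align_pair(genes, mirna)
  }
  prep <- function(x) {
    x <- remove_missing(x)
    if (prevalence) x <- prevalence_filter(x)
    normalize_expression(x, normalization)
  }
  pair <- structure(list(genes = prep(pair$genes), mirna = prep(pair$mirna)),
                    class = "PairedDataset")

  result <- run_mccv(pair, config)
  mirna_table <- aggregate_mirna_ranks(result)
  gene_table <- aggregate_gene_ranks(result)
  perf <- summarize_performance(result)
  assoc <- association_scores(result, depth = config$j_max)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(output_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(mirna_table, "mirna_ranking.tsv")
    wt(gene_table, "gene_ranking.tsv")
    wt(perf, "performance.tsv")
    wt(assoc, "association_scores.tsv")
    resolved <- c(unclass(config),
                  list(normalization = normalization, prevalence = prevalence,
                       genes_file = genes_file, mirna_file = mirna_file))
    yaml::write_yaml(resolved, file.path(output_dir, "config.yaml"))
  }
  invisible(list(result = result, mirna_ranking = mirna_table,
                 gene_ranking = gene_table, performance = perf,
                 association_scores = assoc))
}

#' Validate a trained gene signature on an external cohort
#'
#' Runs the full pipeline on the training pair, truncates the aggregated
#' significant-gene list to `gene_list_depth`, trains the classifier on the
#' training gene matrix restricted to that list, and evaluates it on the
#' external gene matrix (which must share the gene namespace). Optionally
#' the same evaluation is repeated for size-matched random gene lists and
#' averaged, providing the chance baseline the signature is compared
#' against.
#'
#' @param train_pair A `PairedDataset` (raw scale; preprocessing is applied
#'   internally as in [run_pipeline()]).
#' @param external_genes An `ExpressionMatrix` of external-cohort gene
#'   expression (raw scale; normalized internally with the same method).
#' @param gene_list_depth Number of top significant genes to use.
#' @param config An [mccv_config()] for the training run.
#' @param normalization Passed to [normalize_expression()].
#' @param random_repeats Number of random size-matched lists to average
#'   (0 skips the baseline).
#' @param seed Seed for the random baseline draws.
#' @return List with `gene_list`, `metrics` and `auc` for the signature,
#'   and (when requested) `random_metrics`, the element-wise mean confusion
#'   metrics over the random lists.
#' @export
external_validation <- function(train_pair, external_genes, gene_list_depth = 30L,
                                config = mccv_config(n_iterations = 10L),
                                normalization = "log2p1_zscore",
                                random_repeats = 5L, seed = 1L) {
  stopifnot(inherits(train_pair, "PairedDataset"),
            inherits(external_genes, "ExpressionMatrix"))
  run <- run_pipeline(pair = train_pair, config = config,
                      normalization = normalization)
  gene_rank <- run$gene_ranking
  # only genes that were ever grouped carry signal; p-value 1 rows are noise
  ranked <- gene_rank$Gene[gene_rank$`Score (p-value)` < 1]
  if (length(ranked) == 0L)
    stop("pipeline error: no significant genes to validate")
  gene_list <- utils::head(ranked, gene_list_depth)

  present <- intersect(gene_list, feature_ids(external_genes))
  if (length(present) < 0.5 * length(gene_list))
    stop("data error: fewer than half of the listed genes present ",
         "externally; missing: ",
         paste(setdiff(gene_list, present), collapse = ", "))

  train_genes <- normalize_expression(remove_missing(train_pair$genes),
                                      normalization)
  external <- normalize_expression(remove_missing(external_genes),
                                   normalization)
  top <- fit_and_eval(train_genes, external, gene_list,
                      classifier = config$classifier,
                      seed = derive_seed(seed, "top"))
  out <- list(gene_list = gene_list, metrics = top$metrics, auc = top$auc)

  if (random_repeats > 0L) {
    pool <- intersect(feature_ids(train_genes), feature_ids(external))
    reps <- lapply(seq_len(random_repeats), function(k) {
      rl <- with_seed(derive_seed(seed, "random", k),
                      sample(pool, length(gene_list)))
      fit_and_eval(train_genes, external, rl,
                   classifier = config$classifier,
                   seed = derive_seed(seed, "random_fit", k))
    })
    avg <- function(field) mean(vapply(reps, function(x) x$metrics[[field]],
                                       numeric(1)))
    out$random_metrics <- list(
      accuracy = avg("accuracy"), sensitivity = avg("sensitivity"),
      specificity = avg("specificity"),
      auc = mean(vapply(reps, `[[`, numeric(1), "auc")))
  }
  out
}
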