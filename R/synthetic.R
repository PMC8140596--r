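# Synthetic paired miRNA/mRNA generator with planted regulator structure.
# Gaussian generative model on a log-like continuous scale: the pipeline
# consumes normalized expression, so counts are not simulated.

#' Specification for a synthetic paired dataset
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: 200 samples per class, 50 miRNAs of which 5 are
#' planted regulators with a standardized class shift d = 1.5, and 1,000
#' genes of which 20 per planted miRNA are targets generated at population
#' Pearson correlation -0.8 with their regulator. All remaining features
#' are i.i.d. Gaussian decoys with no class effect.
#'
#' @param n_per_class Samples per class.
#' @param n_mirna,n_genes Feature counts of the two matrices.
#' @param n_planted Number of planted regulator miRNAs.
#' @param targets_per_planted Target genes per planted miRNA (targets are
#'   disjoint across regulators so recovery scoring is unambiguous).
#' @param target_correlation Population Pearson r between a planted miRNA
#'   and each of its targets; in (-1, 0).
#' @param class_effect Standardized mean difference (Cohen's d) applied to
#'   planted miRNAs in the positive class.
#' @param noise_sd Standard deviation of the Gaussian noise, in the units
#'   of the log-like expression scale.
#' @param baseline Constant added to shift values non-negative
#'   (expression-like); values are clipped at 0.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @export
synthetic_spec <- function(n_per_class = 200L, n_mirna = 50L, n_genes = 1000L,
                           n_planted = 5L, targets_per_planted = 20L,
                           target_correlation = -0.8, class_effect = 1.5,
                           noise_sd = 1, baseline = 6, seed = 1L) {
  if (target_correlation <= -1 || target_correlation >= 0)
    stop("parameter error: target_correlation must lie in (-1, 0)")
  if (n_planted * targets_per_planted > n_genes)
    stop("parameter error: more target genes than genes available")
  if (n_planted > n_mirna)
    stop("parameter error: more planted miRNAs than miRNAs")
  if (noise_sd <= 0) stop("parameter error: noise_sd must be positive")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_mirna = as.integer(n_mirna), n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 targets_per_planted = as.integer(targets_per_planted),
                 target_correlation = target_correlation,
                 class_effect = class_effect, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a paired two-class dataset with planted regulators
#'
#' Planted miRNAs are Gaussian with a between-class shift of
#' `class_effect` standard deviations (up in the positive class). Each of
#' their target genes is a negative linear transform of the
#' population-standardized miRNA profile plus Gaussian noise, calibrated so
#' the population Pearson correlation equals `target_correlation`; the
#' anti-correlation therefore induces a down-shift of the targets in the
#' positive class, the repression signature the pipeline looks for. Decoy
#' miRNAs and genes are i.i.d. noise with no class structure. All values
#' are shifted by `baseline` and clipped at zero so they resemble
#' non-negative normalized expression on a log-like scale (analyses of
#' synthetic data should therefore use `normalize_expression(.,"zscore")`).
#'
#' @param spec A [synthetic_spec()].
#' @param truth Optional ground truth from a previous call; when supplied,
#'   the same planted miRNAs and target map are reused with fresh samples
#'   (for train/external-cohort experiments).
#' @return List with `pair` (a `PairedDataset`) and `truth` (list with
#'   `planted_mirnas` and `target_map`).
#' @export
generate_synthetic_pair <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- 2L * spec$n_per_class
    classes <- factor(rep(c("neg", "pos"), each = spec$n_per_class),
                      levels = c("neg", "pos"))
    ids <- sprintf("S%04d", seq_len(n))
    mirna_ids <- sprintf("miR-%03d", seq_len(spec$n_mirna))
    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))

    if (is.null(truth)) {
      planted <- sort(sample(mirna_ids, spec$n_planted))
      target_pool <- sample(gene_ids, spec$n_planted * spec$targets_per_planted)
      target_map <- split(target_pool,
                          rep(planted, each = spec$targets_per_planted))
      truth <- list(planted_mirnas = planted, target_map = target_map)
    } else {
      if (!all(truth$planted_mirnas %in% mirna_ids) ||
          !all(unlist(truth$target_map) %in% gene_ids))
        stop("parameter error: supplied truth does not fit this spec")
    }

    d <- spec$class_effect
    sdn <- spec$noise_sd
    rho <- spec$target_correlation
    shift <- ifelse(classes == "pos", d * sdn, 0)

    mirna <- matrix(stats::rnorm(n * spec$n_mirna, sd = sdn),
                    nrow = n, dimnames = list(ids, mirna_ids))
    for (m in truth$planted_mirnas)
      mirna[, m] <- mirna[, m] + shift

    genes <- matrix(stats::rnorm(n * spec$n_genes, sd = sdn),
                    nrow = n, dimnames = list(ids, gene_ids))
    # population mean and sd of a planted miRNA under the balanced
    # two-class mixture
    mu_m <- sdn * d / 2
    sd_m <- sdn * sqrt(1 + d^2 / 4)
    for (m in truth$planted_mirnas) {
      m_std <- (mirna[, m] - mu_m) / sd_m
      for (g in truth$target_map[[m]])
        genes[, g] <- sdn * (rho * m_std +
                               sqrt(1 - rho^2) * stats::rnorm(n))
    }

    mirna <- pmax(mirna + spec$baseline, 0)
    genes <- pmax(genes + spec$baseline, 0)
    pair <- align_pair(expression_matrix(genes, classes, positive = "pos"),
                       expression_matrix(mirna, classes, positive = "pos"))
    list(pair = pair, truth = truth)
  })
}

#' Write a synthetic dataset as input-format files plus ground truth
#'
#' Writes the gene and miRNA tables in the standard delimited layout and a
#' two-column ground-truth sidecar (`truth.tsv`: planted miRNA, comma-joined
#' target genes).
#'
#' @param dataset Result of [generate_synthetic_pair()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_synthetic_pair <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(dataset$pair$genes, file.path(dir, "genes.csv"))
  write_expression_table(dataset$pair$mirna, file.path(dir, "mirna.csv"))
  df <- data.frame(
    miRNA = names(dataset$truth$target_map),
    Targets = vapply(dataset$truth$target_map, paste, "", collapse = ", "),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
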