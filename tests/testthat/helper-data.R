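# Shared fixture builders; everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

em_subset_features_for_test <- function(em, feats) {
  em$values <- em$values[, feats, drop = FALSE]
  em
}

# Tiny deterministic two-class matrix. Feature "sep" separates the classes
# perfectly (neg < 0 < pos); the rest are fixed noise.
toy_em <- function(n_per_class = 10L, n_noise = 2L, seed = 42L) {
  n <- 2L * n_per_class
  set.seed(seed)
  vals <- cbind(
    sep = c(rnorm(n_per_class, -3, 0.3), rnorm(n_per_class, 3, 0.3)),
    matrix(rnorm(n * n_noise), nrow = n,
           dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  rownames(vals) <- sprintf("s%02d", seq_len(n))
  expression_matrix(vals, rep(c("neg", "pos"), each = n_per_class),
                    positive = "pos")
}

# Pure-noise matrix (global null).
null_em <- function(n_per_class = 10L, n_feat = 3L, seed = 99L) {
  n <- 2L * n_per_class
  set.seed(seed)
  vals <- matrix(rnorm(n * n_feat), nrow = n,
                 dimnames = list(sprintf("s%02d", seq_len(n)),
                                 paste0("f", seq_len(n_feat))))
  expression_matrix(vals, rep(c("neg", "pos"), each = n_per_class),
                    positive = "pos")
}

# Write the canonical 4-sample input-layout CSV and return its path.
table3_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "Case ID,Class,A1BG,A2LD1,ZZZ3",
    "TCGA-DK-A6AV,neg,32.877,28.283,721.166",
    "TCGA-DK-A3WX,neg,39.634,57.526,593.293",
    "TCGA-GC-A3WC,pos,29.789,98.344,1057.069",
    "TCGA-BT-A20N,pos,37.378,55.011,755.688"), path)
  path
}

# Small strong-signal paired dataset for pipeline-level tests.
small_signal_data <- function(seed = 7L, n_per_class = 60L) {
  generate_synthetic_pair(synthetic_spec(
    n_per_class = n_per_class, n_mirna = 20L, n_genes = 200L,
    n_planted = 3L, targets_per_planted = 8L, seed = seed))
}

# Brute-force AUC by pairwise enumeration (independent oracle).
brute_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(wins)
}
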