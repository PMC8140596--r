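test_that("under-sampling caps the majority class at ratio times the minority", {
  # the reference imbalanced design: 405 controls / 19 cases -> 38 + 19
  set.seed(91)
  vals <- matrix(rnorm(424 * 2), nrow = 424,
                 dimnames = list(sprintf("s%03d", 1:424), c("f1", "f2")))
  em <- expression_matrix(vals, rep(c("ctrl", "case"), c(405, 19)),
                          positive = "case")
  out <- undersample(em, ratio = 2, seed = 1)
  expect_equal(unname(table(out$classes)[c("ctrl", "case")]),
               c(38L, 19L), ignore_attr = TRUE)
  # already balanced: no-op
  bal <- toy_em(20)
  expect_equal(undersample(bal, 2, seed = 1)$values, bal$values)
  # ratio 1 forces equality
  em2 <- expression_matrix(vals[1:40, ], rep(c("a", "b"), c(30, 10)))
  out2 <- undersample(em2, ratio = 1, seed = 2)
  expect_equal(unname(table(out2$classes)), c(10L, 10L), ignore_attr = TRUE)
  expect_error(undersample(bal, ratio = 0.5), "ratio")
})

test_that("under-sampling follows the min(current, ratio x minority) rule", {
  set.seed(92)
  for (i in 1:50) {
    n_min <- sample(3:40, 1)
    n_maj <- n_min + sample(0:200, 1)
    vals <- matrix(rnorm((n_min + n_maj)), ncol = 1,
                   dimnames = list(sprintf("s%03d", seq_len(n_min + n_maj)), "f"))
    em <- expression_matrix(vals, rep(c("maj", "min"), c(n_maj, n_min)))
    out <- undersample(em, ratio = 2, seed = i)
    tab <- table(out$classes)
    expect_equal(unname(tab[["min"]]), n_min)
    expect_equal(unname(tab[["maj"]]), min(n_maj, 2L * n_min))
  }
})

test_that("stratified splits are proportional, disjoint and exhaustive", {
  em <- toy_em(50)   # 100 samples, 50/50
  sp <- stratified_split(em, 0.9, seed = 101)
  expect_equal(unname(table(sp$train$classes)), c(45L, 45L), ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$classes)), c(5L, 5L), ignore_attr = TRUE)
  expect_length(intersect(sample_ids(sp$train), sample_ids(sp$test)), 0)
  expect_setequal(c(sample_ids(sp$train), sample_ids(sp$test)), sample_ids(em))
  # floor rule on an odd class: 19 cases at 0.9 -> 17 train / 2 test
  set.seed(5)
  vals <- matrix(rnorm(38), ncol = 1,
                 dimnames = list(sprintf("s%02d", 1:38), "f"))
  em19 <- expression_matrix(vals, rep(c("neg", "pos"), 19))
  sp19 <- stratified_split(em19, 0.9, seed = 7)
  expect_equal(sum(sp19$train$classes == "pos"), 17L)
  expect_equal(sum(sp19$test$classes == "pos"), 2L)
  # partition contract across random cases
  for (i in 1:20) {
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    v <- matrix(rnorm(n1 + n2), ncol = 1,
                dimnames = list(sprintf("x%02d", seq_len(n1 + n2)), "f"))
    e <- expression_matrix(v, rep(c("a", "b"), c(n1, n2)))
    s <- stratified_split(e, runif(1, 0.5, 0.95), seed = i)
    expect_length(intersect(sample_ids(s$train), sample_ids(s$test)), 0)
    expect_setequal(c(sample_ids(s$train), sample_ids(s$test)), sample_ids(e))
    expect_true(all(table(s$train$classes) >= 1))
    expect_true(all(table(s$test$classes) >= 1))
  }
})

test_that("the Monte-Carlo loop produces distinct, reproducible iterations", {
  ds <- small_signal_data(seed = 7)
  pair <- ds$pair
  pair$genes <- normalize_expression(pair$genes, "zscore")
  pair$mirna <- normalize_expression(pair$mirna, "zscore")
  cfg <- mccv_config(n_iterations = 3, master_seed = 202, j_max = 3)
  res <- suppressWarnings(run_mccv(pair, cfg))
  expect_s3_class(res, "mccv_result")
  expect_length(res, 3)
  # distinct splits under distinct derived seeds
  expect_false(identical(sort(res[[1]]$test_ids), sort(res[[2]]$test_ids)))
  expect_false(identical(res[[1]]$seed, res[[2]]$seed))
  # bitwise reproducibility under the same master seed
  res2 <- suppressWarnings(run_mccv(pair, cfg))
  expect_identical(res, res2)
  # rankings have no duplicate entries
  for (r in res) {
    expect_equal(anyDuplicated(names(r$mirna_ranking)), 0L)
    expect_equal(anyDuplicated(names(r$gene_ranking)), 0L)
  }
  # under-sampling invariant inside every iteration
  for (r in res) {
    cls <- pair$genes$classes[match(c(r$train_ids, r$test_ids),
                                    sample_ids(pair$genes))]
    tab <- table(cls)
    expect_lte(max(tab) / min(tab), cfg$undersample_ratio)
  }
})

test_that("every iteration ranks a planted miRNA near the top under strong signal", {
  ds <- small_signal_data(seed = 19)
  pair <- ds$pair
  pair$genes <- normalize_expression(pair$genes, "zscore")
  pair$mirna <- normalize_expression(pair$mirna, "zscore")
  res <- suppressWarnings(
    run_mccv(pair, mccv_config(n_iterations = 4, master_seed = 31, j_max = 3)))
  for (r in res) {
    expect_false(r$empty)
    top3 <- names(r$mirna_ranking)[r$mirna_ranking <= 3]
    expect_gte(length(intersect(top3, ds$truth$planted_mirnas)), 1L)
  }
})

test_that("gene ranks are inherited from the miRNA group at best rank", {
  ds <- small_signal_data(seed = 23)
  pair <- ds$pair
  pair$genes <- normalize_expression(pair$genes, "zscore")
  pair$mirna <- normalize_expression(pair$mirna, "zscore")
  res <- suppressWarnings(
    run_mccv(pair, mccv_config(n_iterations = 2, master_seed = 47, j_max = 3)))
  r <- res[[1]]
  for (g in names(r$gene_ranking)) {
    holders <- names(r$groups)[vapply(r$groups, function(gl) g %in% gl,
                                      logical(1))]
    expect_equal(unname(r$gene_ranking[g]),
                 min(unname(r$mirna_ranking[holders])))
  }
})
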