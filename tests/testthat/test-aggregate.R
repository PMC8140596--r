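test_that("normalized ranks divide by the universe and default absences to 1", {
  l1 <- c(a = 1, b = 2); l2 <- c(a = 1); l3 <- c(a = 1, c = 3)
  expect_equal(normalized_ranks("a", list(l1, l2, l3), 10),
               c(0.1, 0.1, 0.1))
  expect_equal(normalized_ranks("b", list(c(b = 2, a = 1), c(a = 1)), 4),
               c(0.5, 1.0))
  expect_equal(normalized_ranks("zz", list(l1, l2), 10), c(1, 1))
  expect_error(normalized_ranks("a", list(), 10), "empty list collection")
  expect_error(normalized_ranks("a", list(c(a = 5)), 3), "universe_size")
})

test_that("the rho score equals the minimum beta order-statistic tail", {
  expect_equal(rho_score(0.05), 0.05)
  # n = 2: p1 = 1 - 0.9^2 = 0.19, p2 = 0.5^2 = 0.25
  expect_equal(rho_score(c(0.1, 0.5)), 0.19)
  expect_equal(rho_score(c(1, 1, 1)), 1)
  expect_error(rho_score(c(0.5, 0.1)), "sorted")
  expect_error(rho_score(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(rho_score(numeric()), "empty")
})

test_that("rho matches exact binomial-tail enumeration", {
  set.seed(111)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    r <- sort(runif(n))
    # independent oracle: explicit binomial upper-tail sums
    pk <- vapply(seq_len(n), function(k)
      sum(choose(n, k:n) * r[k]^(k:n) * (1 - r[k])^(n - (k:n))),
      numeric(1))
    expect_equal(rho_score(r), min(pk), tolerance = 1e-12)
  }
})

test_that("aggregation is permutation-invariant and detects dominance", {
  set.seed(121)
  universe <- paste0("m", 1:20)
  lists <- lapply(1:30, function(i) {
    ord <- sample(universe)
    ord <- c("m1", setdiff(ord, "m1"))        # m1 always first
    stats::setNames(seq_along(ord), ord)
  })
  agg <- aggregate_ranks(lists, universe)
  expect_equal(agg$id[1], "m1")
  expect_lt(agg$p_value[1], 1e-10)
  expect_true(all(diff(agg$p_value) >= 0))
  expect_true(all(agg$p_value > 0 & agg$p_value <= 1))
  # permutation invariance to list order
  agg2 <- aggregate_ranks(rev(lists), universe)
  expect_equal(agg, agg2)
})

test_that("aggregated p-values are conservative under the global null", {
  set.seed(131)
  universe <- paste0("m", 1:30)
  n_rep <- 40L
  frac_sig <- vapply(seq_len(n_rep), function(i) {
    lists <- lapply(1:15, function(j) {
      ord <- sample(universe)
      stats::setNames(seq_along(ord), ord)
    })
    mean(aggregate_ranks(lists, universe)$p_value < 0.05)
  }, numeric(1))
  # binomial noise allowance on top of the nominal rate
  expect_lte(mean(frac_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / (30 * n_rep)))
})

test_that("run-level miRNA and gene aggregation match manual aggregation", {
  ds <- small_signal_data(seed = 29)
  pair <- ds$pair
  pair$genes <- normalize_expression(pair$genes, "zscore")
  pair$mirna <- normalize_expression(pair$mirna, "zscore")
  res <- suppressWarnings(
    run_mccv(pair, mccv_config(n_iterations = 3, master_seed = 3, j_max = 3)))

  mtab <- aggregate_mirna_ranks(res)
  expect_equal(names(mtab), c("miRNA", "Score (p-value)", "Targets", "#Genes"))
  manual <- aggregate_ranks(lapply(res, `[[`, "mirna_ranking"),
                            attr(res, "mirna_universe"))
  expect_equal(mtab$miRNA, manual$id)
  expect_equal(mtab$`Score (p-value)`, manual$p_value)
  expect_equal(mtab$`#Genes`,
               lengths(strsplit(mtab$Targets, ", ", fixed = TRUE)),
               ignore_attr = TRUE)

  gtab <- aggregate_gene_ranks(res)
  gmanual <- aggregate_ranks(lapply(res, `[[`, "gene_ranking"),
                             attr(res, "gene_universe"))
  expect_equal(gtab$Gene, gmanual$id)
  expect_equal(gtab$`Score (p-value)`, gmanual$p_value)
  # a gene never grouped is maximally insignificant
  never <- setdiff(attr(res, "gene_universe"),
                   unlist(lapply(res, function(r) names(r$gene_ranking))))
  if (length(never) > 0)
    expect_equal(unique(gtab$`Score (p-value)`[gtab$Gene %in% never]), 1)
})

test_that("association scores weight persistence in the top groups", {
  mk_rec <- function(ranking) list(mirna_ranking = ranking, empty = FALSE)
  recs <- structure(lapply(1:10, function(i)
    mk_rec(c(always = 1, sometimes = ifelse(i <= 5, 2, 15), never = 20))),
    class = "mccv_result", mirna_universe = c("always", "sometimes", "never"))
  tab <- association_scores(recs, depth = 10)
  expect_equal(tab$miRNA[1], "always")
  # rank 1 in all 10 iterations at depth 10 scores exactly depth
  expect_equal(tab$Score[tab$miRNA == "always"], 10)
  expect_equal(tab$Score[tab$miRNA == "never"], 0)
  s <- tab$Score[tab$miRNA == "sometimes"]   # rank 2 in 5 of 10 iterations
  expect_equal(s, 10 / 10 * 5 * (10 - 2 + 1) / 10)
  expect_true(all(tab$Score >= 0 & tab$Score <= 10))
})
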