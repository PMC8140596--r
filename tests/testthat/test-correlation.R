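test_that("pearson_r matches hand-computed coefficients and flags degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "unequal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the correlation matrix has miRNA-by-gene shape and matches per-pair calls", {
  set.seed(21)
  g <- toy_em(6, n_noise = 2)                 # 3 gene features
  m <- toy_em(6, n_noise = 1, seed = 5)       # 2 miRNA features
  colnames(m$values) <- c("miR-a", "miR-b")
  m$values[, "miR-a"] <- g$values[, "sep"]    # identical profile
  pair <- align_pair(g, m)
  corr <- correlation_matrix(pair)
  expect_equal(dim(corr), c(2L, 3L))
  expect_equal(corr["miR-a", "sep"], 1)
  for (i in rownames(corr)) for (j in colnames(corr))
    expect_equal(corr[i, j],
                 pearson_r(pair$mirna$values[, i], pair$genes$values[, j]))
})

test_that("grouping keeps genes at or below the threshold and drops empty groups", {
  corr <- rbind(m1 = c(-0.7, -0.2, -0.61), m2 = c(0.1, -0.59, 0.9))
  colnames(corr) <- c("g1", "g2", "g3")
  groups <- build_groups(corr)
  expect_s3_class(groups, "TargetGeneGroups")
  expect_equal(groups[["m1"]], c("g1", "g3"))   # inclusive at -0.61 <= -0.6
  expect_false("m2" %in% names(groups))
  # boundary is inclusive
  corr["m2", "g2"] <- -0.6
  expect_equal(build_groups(corr)[["m2"]], "g2")
  # undefined correlations never pass
  corr["m2", "g2"] <- NA
  expect_false("m2" %in% names(build_groups(corr)))
  # nothing passes -> pipeline error
  expect_error(build_groups(corr * 0 + 0.5), "no miRNA-mRNA associations")
  expect_error(build_groups(corr, threshold = 0.3), "between -1 and 0")
})

test_that("relaxing the threshold toward zero never shrinks a group", {
  set.seed(8)
  corr <- matrix(runif(200, -1, 1), nrow = 10,
                 dimnames = list(paste0("m", 1:10), paste0("g", 1:20)))
  thresholds <- c(-0.9, -0.6, -0.3, -0.1)
  prev <- NULL
  for (th in thresholds) {
    cur <- tryCatch(build_groups(corr, th), error = function(e) NULL)
    if (!is.null(prev) && !is.null(cur)) {
      for (m in names(prev))
        expect_true(all(prev[[m]] %in% cur[[m]]))
    }
    prev <- cur
  }
})

test_that("planted target memberships are recovered at the default threshold", {
  ds <- generate_synthetic_pair(synthetic_spec(seed = 13))
  pair <- ds$pair
  pair$genes <- normalize_expression(pair$genes, "zscore")
  pair$mirna <- normalize_expression(pair$mirna, "zscore")
  corr <- correlation_matrix(pair)
  groups <- build_groups(corr, -0.6)
  truth <- ds$truth$target_map
  planted_pairs <- sum(lengths(truth))
  hits <- 0L; false_members <- 0L; total_members <- 0L
  for (m in names(groups)) {
    total_members <- total_members + length(groups[[m]])
    tm <- truth[[m]] %||% character()
    hits <- hits + sum(groups[[m]] %in% tm)
    false_members <- false_members + sum(!groups[[m]] %in% tm)
  }
  expect_gte(hits / planted_pairs, 0.95)
  expect_lte(false_members / max(total_members, 1L), 0.05)
})

test_that("target-group export matches the two-column layout", {
  groups <- structure(list(`miR-x` = c("SYNJ2BP", "NLGN1", "KCNK3")),
                      class = "TargetGeneGroups")
  p <- tempfile(fileext = ".tsv")
  write_target_groups(groups, p)
  back <- read.delim(p, check.names = FALSE)
  expect_equal(names(back), c("miRNA", "Targets"))
  expect_equal(back$Targets, "SYNJ2BP, NLGN1, KCNK3")
})
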