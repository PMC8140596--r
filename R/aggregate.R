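# Robust rank aggregation across Monte-Carlo iterations via beta
# order-statistic tail probabilities (the rho score), plus the
# frequency-weighted per-miRNA association score.
#
# Ranked lists are represented as named numeric vectors: names are item
# ids, values are ranks (1 = best). miRNA lists carry dense ranks
# 1..n_groups; gene lists carry the rank inherited from the miRNA group.

#' Normalized ranks of one item across ranked lists
#'
#' For every list the item's rank divided by the universe size; lists that
#' do not contain the item contribute the uninformative worst case 1.0.
#' The result is sorted ascending, ready for [rho_score()].
#'
#' @param item Item identifier.
#' @param lists List of ranked lists (named numeric rank vectors).
#' @param universe_size Total number of candidate items; must be at least
#'   the length (and maximal rank) of every list.
#' @return Sorted numeric vector in (0, 1\], one entry per list.
#' @export
normalized_ranks <- function(item, lists, universe_size) {
  if (length(lists) == 0L)
    stop("data error: empty list collection")
  sizes <- vapply(lists, length, integer(1))
  maxr <- vapply(lists, function(l) if (length(l)) max(l) else 0, numeric(1))
  if (universe_size < max(c(sizes, maxr)))
    stop("data error: universe_size smaller than a ranked list")
  r <- vapply(lists, function(l) {
    v <- l[item]
    if (is.na(v)) 1.0 else unname(v) / universe_size
  }, numeric(1))
  sort(unname(r))
}

#' Rho score of a sorted normalized rank vector
#'
#' For sorted normalized ranks r(1) <= ... <= r(n), computes for every k
#' the probability that the k-th order statistic of n independent
#' uniform(0,1) variables is at most r(k) -- the upper binomial tail
#' P(Binomial(n, r(k)) >= k), evaluated through the equivalent beta
#' order-statistic CDF -- and returns the minimum over k. Small rho means
#' the item sits consistently nearer the top of the lists than uniform
#' ranking would place it.
#'
#' @param sorted_norm_ranks Ascending numeric vector with entries in (0, 1\].
#' @return rho in (0, 1\].
#' @export
rho_score <- function(sorted_norm_ranks) {
  r <- sorted_norm_ranks
  n <- length(r)
  if (n == 0L) stop("data error: empty rank vector")
  if (is.unsorted(r))
    stop("contract violation: normalized ranks must be sorted ascending")
  if (any(r <= 0 | r > 1))
    stop("contract violation: normalized ranks must lie in (0, 1]")
  k <- seq_len(n)
  min(stats::pbeta(r, k, n - k + 1))
}

#' Aggregate ranked lists into per-item p-values
#'
#' Computes each universe item's rho score over the lists and converts it
#' to an aggregated p-value by a Bonferroni correction over the n order
#' statistics considered: p = min(1, rho * n). Rows are sorted by
#' ascending p-value; ties are broken by smaller mean normalized rank,
#' then lexicographic id.
#'
#' @param lists List of ranked lists (named numeric rank vectors), one per
#'   iteration.
#' @param universe Character vector of all candidate item ids.
#' @return Data frame with columns `id`, `rho`, `p_value`, `mean_rank`,
#'   sorted ascending by `p_value`.
#' @export
aggregate_ranks <- function(lists, universe) {
  if (length(lists) == 0L)
    stop("data error: at least one ranked list required")
  universe_size <- length(universe)
  rows <- lapply(universe, function(item) {
    r <- normalized_ranks(item, lists, universe_size)
    data.frame(id = item, rho = rho_score(r),
               p_value = min(1, rho_score(r) * length(r)),
               mean_rank = mean(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$mean_rank, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate the per-iteration miRNA rankings
#'
#' Applies [aggregate_ranks()] to the miRNA ranked lists of a Monte-Carlo
#' run and reports the canonical output schema: each miRNA with its
#' aggregated p-value score, the union of target genes it was ever grouped
#' with, and the size of that gene set.
#'
#' @param records An `mccv_result`.
#' @param universe Optional miRNA universe (defaults to all miRNAs that
#'   survived preprocessing, attached to the run).
#' @return Data frame with columns `miRNA`, `Score (p-value)`, `Targets`,
#'   `#Genes`, sorted ascending by p-value.
#' @export
aggregate_mirna_ranks <- function(records, universe = NULL) {
  stopifnot(inherits(records, "mccv_result"))
  universe <- universe %||% attr(records, "mirna_universe")
  lists <- lapply(records, `[[`, "mirna_ranking")
  agg <- aggregate_ranks(lists, universe)
  targets <- lapply(stats::setNames(nm = agg$id), function(m) {
    unique(unlist(lapply(records, function(r) r$groups[[m]]),
                  use.names = FALSE))
  })
  out <- data.frame(
    miRNA = agg$id,
    `Score (p-value)` = agg$p_value,
    Targets = vapply(targets, function(g) paste(g, collapse = ", "), ""),
    `#Genes` = lengths(targets),
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate the inherited-rank gene rankings
#'
#' Genes inherit, in every iteration, the rank of the miRNA group they
#' belong to (best rank on multiple membership); those per-iteration lists
#' are aggregated exactly like the miRNA lists. The supporting miRNAs of
#' each gene (the groups it was ever a member of) are reported alongside.
#'
#' @inheritParams aggregate_mirna_ranks
#' @return Data frame with columns `Gene`, `Score (p-value)`, `miRNAs`,
#'   sorted ascending by p-value.
#' @export
aggregate_gene_ranks <- function(records, universe = NULL) {
  stopifnot(inherits(records, "mccv_result"))
  universe <- universe %||% attr(records, "gene_universe")
  lists <- lapply(records, `[[`, "gene_ranking")
  agg <- aggregate_ranks(lists, universe)
  support <- lapply(stats::setNames(nm = agg$id), function(g) {
    unique(unlist(lapply(records, function(r)
      names(r$groups)[vapply(r$groups, function(gl) g %in% gl, logical(1))]),
      use.names = FALSE))
  })
  out <- data.frame(
    Gene = agg$id,
    `Score (p-value)` = agg$p_value,
    miRNAs = vapply(support, function(m) paste(m, collapse = ", "), ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Frequency-weighted miRNA association scores
#'
#' A persistence measure of how consistently a miRNA occupies the
#' top-ranked groups across iterations:
#' score = (depth / n_iterations) * sum over iterations of
#' (depth - rank + 1) / depth for iterations where the miRNA ranks within
#' the top `depth`. A miRNA ranked first in every iteration scores exactly
#' `depth` (10 at the default depth); one never in the top-depth scores 0.
#' This score is a reconstruction of a frequency-based ranking heuristic;
#' it is plumbing around the aggregated p-values, not a probability.
#'
#' @param records An `mccv_result`.
#' @param depth Top-rank cutoff (default 10).
#' @return Data frame with columns `miRNA` and `Score`, sorted descending.
#' @export
association_scores <- function(records, depth = 10L) {
  stopifnot(inherits(records, "mccv_result"), depth >= 1L)
  n_iter <- length(records)
  if (n_iter == 0L) stop("data error: no iteration records")
  universe <- attr(records, "mirna_universe") %||%
    unique(unlist(lapply(records, function(r) names(r$mirna_ranking))))
  score <- stats::setNames(numeric(length(universe)), universe)
  for (r in records) {
    rk <- r$mirna_ranking
    rk <- rk[rk <= depth]
    if (length(rk) == 0L) next
    w <- (depth - rk + 1) / depth
    score[names(rk)] <- score[names(rk)] + w
  }
  score <- score * depth / n_iter
  out <- data.frame(miRNA = names(score), Score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$Score, out$miRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}
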