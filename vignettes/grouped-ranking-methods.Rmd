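---
title: "Correlation-grouped ranking of miRNA target-gene signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-grouped ranking of miRNA target-gene signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

miRNAs repress their target mRNAs post-transcriptionally, so across a
cohort a regulating miRNA and its targets tend to be *anti-correlated*.
`mirank` turns this into a supervised feature-grouping scheme for paired
two-class (case/control) expression studies measured on the same samples:

1. **Grouping (G).** After preprocessing, the Pearson correlation between
   every miRNA and every mRNA is computed. The *group* of miRNA $m$ is
   $\{g : r(m, g) \le \tau\}$ with $\tau = -0.6$ by default — a stringent
   cutoff chosen for high-confidence associations. Groups are the unit of
   feature selection; a gene may belong to several groups, and miRNAs with
   empty groups are dropped.
2. **Ranking (R).** Each group is scored by how well a classifier trained
   *only on that group's genes* separates the two classes: $r = 5$
   stratified 80:20 hold-out splits of the training data, confusion counts
   pooled over the repeats (micro-average), and groups sorted by accuracy.
   Ties break by higher F-measure, then larger group, then miRNA id — a
   deterministic, documented order.
3. **Cumulative top-$j$ models.** For $j = 1 \dots 10$, a classifier is
   trained on the union of the genes of the $j$ best groups and evaluated
   on held-out samples, giving a performance ladder over signature size.
4. **Monte-Carlo cross-validation.** The whole chain runs inside $N$
   iterations (default 100) of a stratified 90/10 split preceded by 1:2
   majority-class under-sampling. Everything on the training side —
   differential-expression filtering, correlations, grouping, ranking,
   model fitting — sees only the training part; test samples are used
   exclusively for top-$j$ evaluation.
5. **Rank aggregation.** Each iteration yields a miRNA ranking (and a gene
   ranking, each gene inheriting its group's rank, deduplicated at its
   best rank). Per item, the sorted normalized ranks $r_{(1)} \le \dots
   \le r_{(n)}$ over the $n$ iterations (absences count as the
   uninformative worst case 1.0) give
   $\rho = \min_k P\!\left(\mathrm{Beta}(k,\, n - k + 1) \le r_{(k)}\right)$,
   the minimum beta order-statistic tail — equivalently the upper binomial
   tail $P(\mathrm{Bin}(n, r_{(k)}) \ge k)$. The aggregated p-value is the
   Bonferroni-corrected $\min(1, \rho \, n)$. Small values mean the item
   sat consistently nearer the top than uniform ranking would place it.

### Preprocessing

The fixed order is: drop features with missing values (features, not
samples — samples are the scarce resource in case/control designs; the
choice is configurable in spirit by pre-cleaning the input), optionally a
prevalence filter on the raw scale (value $\ge 1$ in $\ge 50\%$ of
samples, the conventional RNA-seq cutoff), normalization, then a
per-feature two-sample t-test keeping features with $p \le 0.05$. Welch's
unequal-variance form is the default — the safer choice for expression
data — with the pooled form available. Normalization defaults to
$\log_2(x+1)$ followed by per-feature standardization, the conventional
treatment of RPKM/RPM-scale input; `"zscore"` (for data already on a
log-like scale) and `"none"` (pre-normalized input) are provided.
Correlations are computed on the normalized matrices.

### Classifiers

Group scoring and top-$j$ models use a random forest (100 trees, default
mtry) by default; a linear-kernel SVM is the alternative. The forest is
the primary choice for prediction quality on expression panels; the SVM
variant is retained because the ranking procedure is classically defined
with it. No hyperparameter tuning is performed anywhere: the method
compares *feature sets*, and tuning inside the ranking loop would
confound group quality with model selection.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cor_threshold` | -0.6 | inclusive anti-correlation cutoff for group membership |
| `alpha` | 0.05 | DE t-test cutoff (inclusive) |
| `n_iterations` | 100 | outer Monte-Carlo iterations |
| `train_fraction` | 0.9 | outer stratified split |
| `undersample_ratio` | 2 | majority:minority cap (1:2 under-sampling) |
| `r`, `f` | 5, 0.8 | internal scoring repeats and split |
| `j_max` | 10 | cumulative top-group depth |
| `classifier` | random_forest | or `svm` |

## Numerical and design choices

- **Threshold semantics.** Group membership is $r \le -0.6$ inclusive:
  "magnitude at least 0.6, negative sign". Undefined correlations
  (constant profiles) never pass.
- **Stratified split rounding.** Per class, the training part receives
  $\lfloor f\, n_c \rfloor$ samples, clamped so both parts keep at least
  one sample per class; the remainder is the test part (19 cases at 0.9
  give 17 train / 2 test).
- **Under-sampling scope.** Under-sampling is applied to the whole
  iteration sample before splitting (`undersample_scope = "all"`), so the
  1:2 ratio holds in both parts; `"train_only"` is exposed because either
  reading of the protocol is defensible.
- **Seed policy.** Every stochastic step derives its seed from the master
  seed plus a stable discriminator (iteration index, miRNA id, repeat
  index) through a fixed integer hash. Group scores are therefore
  invariant to group insertion order, and a whole run is bit-reproducible
  from `master_seed` alone.
- **Undefined metrics.** A metric with a zero denominator (e.g. precision
  with no positive predictions) is reported as 0 and flagged, so every
  group keeps a complete score row rather than dropping out.
- **Aggregation universe.** Normalized ranks divide by the full universe
  of features surviving preprocessing, and items missing from a list
  contribute 1.0 — the conservative treatment of partial lists.
- **Association score.** The per-miRNA persistence score
  $\mathrm{score}(m) = \frac{d}{N}\sum_{i:\ \mathrm{rank}_i(m) \le d}
  \frac{d - \mathrm{rank}_i(m) + 1}{d}$ (depth $d = 10$) ranges from 0 to
  $d$, with $d$ attained by a miRNA ranked first in every iteration. This
  formula is a reconstruction of a frequency-based ranking heuristic —
  the underlying published description does not state one — and should be
  read as a descriptive persistence measure, not a probability.
- **Empty iterations.** An iteration in which no association passes the
  threshold is recorded as empty; the run aborts only when more than
  `max_empty_fraction` (default 50%) of iterations are empty. For null
  studies that fraction can legitimately be 100%, so the bound is
  configurable; aggregation over empty lists returns p-value 1 for every
  item, the correct conservative answer.

## The synthetic-data generator

`generate_synthetic_pair()` emulates exactly the structure the method
assumes: a set of planted regulator miRNAs whose expression is shifted
between classes by `class_effect` standard deviations (Cohen's d, default
1.5), each repressing a disjoint block of `targets_per_planted` target
genes generated as a negative linear transform of the standardized miRNA
profile plus Gaussian noise, calibrated so the *population* Pearson
correlation equals `target_correlation` (default -0.8). Anti-correlation
with an up-shifted regulator automatically gives the targets a down-shift
in cases — the repression signature. All other features are i.i.d.
Gaussian decoys. Values are produced on a log-like continuous scale,
shifted non-negative (baseline 6, clipped at 0) to resemble normalized
expression; analyses of synthetic data should therefore use
`normalization = "zscore"`.

The default dimensions — 200 samples per class, 50 miRNAs with 5 planted,
1,000 genes with 20 targets per regulator — are the package's reference
study conditions, sized so a desk-scale machine completes a 20-iteration
Monte-Carlo run in about a minute while the planted structure is neither
trivially easy (single-gene separation) nor undetectable.

What the generator does *not* emulate: count noise (a negative-binomial
mode is future work; the pipeline consumes normalized continuous values),
batch structure, correlated decoys, many-to-many regulation (a target
gene belongs to exactly one regulator so recovery scoring is
unambiguous), and realistic miRNA biogenesis. Passing the planted-recovery
tests therefore demonstrates that the machinery is correct and well
calibrated, not that real tissues will yield groups this clean.

Because targets of one regulator share a single latent factor, their
information content saturates: a 20-gene group is roughly "one strong
latent discriminant", which is why single-group accuracies sit near 0.75
rather than 1.0 at these settings, and why cumulative top-$j$ models
improve with $j$ as independent regulators join the signature.

## Validation included with the package

The test suite checks, among others: the rho score against explicit
binomial-tail enumeration and a Monte-Carlo order-statistic oracle; all
seven confusion metrics against direct arithmetic; AUC against brute-force
pairwise enumeration and an independent ROC implementation; type-I-error
calibration of the DE filter; chance-level behaviour of group scores and
AUC under label permutation; exact under-sampling counts (405/19 gives
38+19 at 1:2); train/test disjointness in every iteration;
bit-reproducibility under a fixed master seed; full planted-regulator
recovery at the reference conditions; null-configuration calibration (no
significant miRNA, chance-level models); and the significant-versus-random
gene-list contrast on an external synthetic cohort at sizes 1/2/5/30.
`scripts/acceptance.R` re-runs the reference computations end to end and
writes the resulting quantities as JSON.

## Known limitations

- Pearson correlation only captures linear (monotone, after
  normalization) repression; rank-based alternatives are not implemented.
- Normalization statistics are computed on the full cohort before the
  Monte-Carlo loop (the protocol's fixed component order); the leakage
  audit therefore covers the DE filter, correlation, grouping, ranking
  and fitting, not the per-feature standardization constants.
- Group scores from tiny test folds are noisy; the micro-average pooling
  mitigates but does not remove this, and rank aggregation across
  iterations is the intended stabilizer.
- The association score is a reconstruction (see above) and should not be
  compared across runs with different depths or iteration counts.
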