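---
title: "MFSS: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MFSS: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfss)
```

## The problem

A multidimensional dataset attaches `m` class variables to every instance —
several diagnoses per patient, several tags per scene. Classical filter
selection ranks features against a single target; applied per class variable
it yields `m` different subsets, and their union typically removes little.
MFSS (multidimensional feature subset selection) produces a **single global
subset** shared by all class variables, so any downstream classifier —
independent per-class models (problem transformation) or one model handling
all classes (algorithm adaptation) — works from one reduced design matrix.

## The model

Given `n` instances, `l` numeric features and `m` class variables:

1. `r_{ji} = cor(f_j, enc(c_i))`, the sample Pearson correlation between
   feature `j` and class variable `i` after numeric encoding.
2. Per class variable, features are ranked by descending `r` and given integer
   rank weights `w_{ji}`: `l` for the best, down to `1` for the worst.
3. The overall weight is the rank-weighted mean
   `w_j = Σ_i w_{ji} r_{ji} / Σ_i w_{ji}` — a convex combination of the
   feature's per-class correlations, so `w_j ∈ [min_i r_{ji}, max_i r_{ji}]`.
4. Features are ranked by descending `w_j` and the top `s = round(log2 l)` are
   selected.

The construction is a pure filter: no classifier is consulted, the cost is one
`l × m` correlation pass plus sorting, and the result is deterministic.

### Assumptions

* Associations are measured linearly. A feature related to a class only
  non-monotonically (e.g. quadratic) scores near zero.
* Class variables are treated independently in step 1–2; label correlations
  enter only through the aggregation in step 3.
* Features must be numeric; nominal features are integer-encoded at load
  time (declaration order). This encoding is a convention of the
  implementation, not a modelling claim — for nominal features with more than
  a few unordered levels the Pearson correlation against integer codes is a
  crude association measure.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `s` (`mfss(x, s =)`) | `round(log2 l)`, half up | subset size; override for sensitivity analyses |
| `absolute` | `FALSE` | rank by `|r|` instead of signed `r` |
| imputation | mean (numeric) / mode (`nominal_features=`) | gap filling for features; class-missing rows are dropped |
| protocol | 10-fold CV, seed 1 | split scheme of the benchmarking harness |

Two defaults deserve comment.

**Rounding of `s = log2 l`.** The threshold is stated as a formula without a
rounding rule. Nearest-integer rounding with halves up is the only rule that
reproduces all five published benchmark counts (28→5 requires rounding 4.81
up; 294→8 requires rounding 8.20 down), so it is the default, exposed in
`subset_size()`.

**Signed correlations.** The ranking sorts signed `r` descending, taken
literally: a strongly *negative* correlate ranks last. Most filter methods
would rank by `|r|`; that behaviour is available via `absolute = TRUE` but is
off by default because the signed sort is the documented procedure. With
`m = 1` the method collapses to plain correlation ranking, making the choice
visible: `mfss(x, absolute = TRUE)` will surface inversely associated
features that the default ignores.

Other conventions: zero-variance features or classes get `r = 0` ("no
association"), all ties (rank weights, final ranking) break toward the lower
feature index so results are identical across platforms and runs.

## The synthetic generator

`generate_synthetic()` emulates the *structure* of the binary multi-label
benchmarks (scene, music, yeast): `m` exactly balanced binary class
variables, a small planted set of informative features, independent Gaussian
noise elsewhere. A feature planted on class `i` with effect `e` is
`e·z_i + N(0, σ)` where `z_i` is the ±1 encoding of the class, so its
population correlation with the class is `e/√(e² + σ²)` — with the default
`effect = 5, noise_sd = 1` that is ≈ 0.98, a strong but noisy signal. The
planted-recovery tests use `n = 500, l = 50, m = 6`, one planted feature per
class: `n` and `l` sit in the range of the smaller benchmarks, and `m = 6`
matches the scene/music label counts while giving each of the
`s = round(log2 50) = 6` selected slots exactly one planted feature to find.

What the generator does **not** emulate: label co-occurrence structure
(benchmark labels are correlated; generated classes are independent),
multi-valued class variables (thyroid, solar flare), heavy-tailed or discrete
feature distributions, and redundant informative features. A green
planted-recovery test therefore establishes that the ranking machinery finds
strong linear signal among independent noise — not that the method handles
redundancy or non-linear structure.

## Statistical validation layer

`validate_metric_table()` reproduces the published validation design: for
each classifier, the vector of per-dataset metrics before selection (`a`) is
compared with the vector after selection (`p`) via

* the Pearson correlation `r_ap`, categorized by the Evans scale
  (|r| 0.00–0.19 very weak … 0.80–1.00 very strong; a boundary value starts
  its own bin, and the bin is decided by |r| — the published analyses only
  meet positive r, so the sign convention is ours);
* the paired t-test on `d = a − p`, `t = Σd / √((kΣd² − (Σd)²)/(k−1))`,
  `df = k − 1`, two-sided critical values from the Student-t quantile
  (2.7764 / 4.6041 at df = 4 for α = 0.05 / 0.01). The direction `a − p`
  reproduces the published signs. `H₀` (no performance difference) is
  accepted when `|t|` does not exceed the critical value.

Degenerate inputs are handled explicitly: identical vectors give `t = 0` with
a `degenerate` flag (zero variance of differences); constant metric vectors
make `r_ap` undefined and are reported as `NA` rather than a number.

The bundled `benchmark_metrics()` table transcribes the published evaluation
metrics of five benchmark datasets × four classifiers × two conditions. One
cell was corrected during transcription: the IBk/music Hamming loss after
selection is printed as 0.252 alongside a Hamming score of 0.74, violating
the exact complement `HS + HL = 1` that every other row satisfies; since
0.74 is the value consistent with the published correlation and t statistics,
the loss cell is stored as 0.26. No other cell was altered.

A note on an internal inconsistency in the published prose: the running text
quotes correlations (0.93, 0.868, 0.868, 0.930 for Hamming score) that do not
match the printed correlation table (0.914, 0.867, 0.801, 0.859). Only the
table values are arithmetically consistent with the underlying metric tables,
so this package's tests target the table.

## Evaluation harness decisions

* **Problem transformation, not super-classes.** The harness trains one
  independent single-target classifier per class variable, the only
  construction the source experiments concretely specify. A label-powerset
  ("super-class") variant is out of scope.
* **Selection inside the resampling loop.** The feature subset is recomputed
  from the training portion of every split, so test instances never influence
  selection. This is stricter than the published experiments (which are
  silent on the issue) and can only make the MFSS condition look worse, never
  better.
* **Protocol.** The published experiments never state their split scheme or
  hyperparameters; the default here is 10-fold cross-validation with a fixed
  seed, with metrics computed on pooled out-of-fold predictions. Holdout is
  available. Because the published raw metric values depend on a specific
  toolkit's classifier implementations and an unstated protocol, they are
  *not* reproduction targets; they enter only as a transcribed fixture for
  the validation layer.
* **Trainers.** Bundled trainers (majority, nearest centroid, kNN, Gaussian
  naive Bayes) are deterministic baselines behind a trainer contract
  (`function(x, y, seed) -> function(newx) -> factor`); J48/SVM-class
  learners plug in through the same contract.

## Numerical choices

* Correlations are computed by the centered (covariance/σ) formulation;
  tests verify agreement with the raw-sum textbook formula to 1e−10 — the
  two are algebraically identical but the centered form is numerically
  stabler.
* `s` clamps to `[1, l]`, so tiny datasets always select at least one
  feature.
* ARFF numerics are written with 17 significant digits so write→read
  round-trips are exact.
* Imputation order: class-missing rows are dropped first, then feature means
  are computed from the remaining rows; the operation is idempotent.

## Known limitations

* Pearson correlation against integer-coded multi-valued classes makes the
  ranking depend on the (arbitrary) domain order of those classes; for
  genuinely nominal class variables an association measure such as η² or
  mutual information would be order-invariant, but is outside this method's
  definition.
* The `log2 l` threshold is a heuristic with no optimality guarantee; the
  `s` override exists precisely to examine its neighbourhood.
* No redundancy handling: two perfectly collinear informative features both
  rank highly and can crowd out a complementary feature.
* The metric-vector correlation and paired t-test operate on `k = 5` paired
  values in the published design; with such small `k` the t-test has little
  power, so "accept H₀" is weak evidence of equivalence — the package
  reports the decision but the caller should read it with that caveat.
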