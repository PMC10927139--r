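---
title: "Grouped particle-swarm feature selection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped particle-swarm feature selection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iggpso)
```

## The selection model

`iggpso` addresses feature selection in the "wide" regime typical of
expression data: thousands of features, at most a couple of hundred samples,
two to four classes. The method has three stages.

**Information-gain ranking.** Every feature is discretized and scored by
`IG(f) = H(C) − H(C|f)` in bits, then sorted in descending order. No feature
is discarded at this stage — the point is to avoid the arbitrary score
threshold that filter selectors require. The estimator needs discrete
feature values, so continuous expression is binned per feature into
`n_bins = 10` equal-width bins between the observed minimum and maximum.
Equal-width binning is the simplest reproducible choice and is standard in
the filter-selection literature; a constant feature maps to a single bin and
scores exactly zero. Zero-probability cells contribute exactly zero to every
entropy sum, and IG values within `-1e-12` of zero are clipped to zero
(floating-point cancellation; IG is theoretically non-negative). Ranking
ties are broken by ascending feature index so results are identical across
platforms.

**Information-index grouping.** With `gamma` (target features per group,
default 100) the group count is `k = ceiling(M / gamma)`, and the
information index `I = sum(IG) / k` is the IG mass each group should carry.
A greedy sweep over the ranked list closes the current group once its
cumulative IG first reaches `I`, subject to leaving at least one feature for
each remaining group; all residual features join the last group. The result
is an exact contiguous partition of the ranked order: early groups are small
and information-dense, late groups large and noisy. When the IG mass is
heavily front-loaded the non-emptiness guarantee takes precedence over the
IG target.

**Grouped binary PSO.** The swarm's active pool starts as group 1. Particles
are bit vectors over the pool (1 = feature selected) with real-valued
velocities; per iteration and particle the velocity update uses scalar
uniforms `r1, r2` and the sigmoid transfer turns each velocity component
into a bit probability. In-group fitness is the stratified cross-validated
accuracy of the selected subset. When the global best has not improved for
`patience` consecutive iterations (or `max_iter` is reached) the phase ends:
its champion subset is scored by the out-group objective
`lambda * ACC - (1 - lambda) * |S| / M`, and — if groups remain — the next
group's features are appended to the pool. Existing particles receive fresh
random bits and velocities in the new dimensions while personal/global best
positions are zero-extended: the zero-extended best selects the same feature
subset as before, so its recorded fitness remains valid, while the new
random dimensions restore diversity. The final selection is the phase
champion with the best out-group fitness, re-evaluated for its reported
accuracy. With `k = 1` the procedure reduces exactly — same RNG draw
sequence, same trajectory — to a plain binary PSO, which is also how the
`pso_select()` baseline is implemented.

Two readings of the final-output contract were possible: return the
per-group champions as a set, or return the single best champion under the
out-group objective. The package returns the single global best (the
per-phase champions remain available in `result$phases`), since the
out-group objective is explicitly designed to make group-level results
comparable.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `ig.bins` (`discretization_scheme`) | 10 | bins | standard equal-width resolution; robust at n ≈ 50–200 samples |
| `gamma` | 100 | features/group | yields group sizes of tens-to-hundreds, matching reported subset scales on 10³–10⁴-feature benchmarks |
| `w` | 0.7 | inertia | canonical binary-PSO setting |
| `c1`, `c2` | 2.0 | acceleration | canonical setting |
| `v_max` | 6 | velocity clamp | sigmoid(±6) ≈ 0.0025/0.9975 keeps bit flips possible |
| `swarm_size` | 20 | particles | canonical 10–40 range |
| `max_iter` | 30 | iterations/phase | see below |
| `patience` | 5 | iterations | see below |
| `lambda` | 0.9 | trade-off ∈ [0,1] | accuracy-dominant; the size term breaks accuracy ties toward small subsets |
| `cv_folds` | 5 | folds | small-sample stability; a single split is too noisy at n ≤ 200 |
| SVM kernel / C | linear / 1 | — | standard for wide expression data; avoids kernel tuning inside the wrapper |
| KNN `k_neighbors` | 5 | neighbors | standard default |

`max_iter = 30` and `patience = 5` are deliberately tighter than the
100-iteration runs sometimes seen in wrapper studies. The stagnation rule
makes long in-group phases unproductive here: once accuracy saturates within
a pool, further iterations cannot improve the phase champion, and the
productive move is to open the next group. Short patience shifts budget
toward the out-group search across pools, which is where this method differs
from a plain PSO; it also keeps a full 20-phase run on a 2000-feature
dataset to roughly a minute on one CPU. Both are ordinary configuration
fields for users who want longer searches.

## Evaluation protocol

Accuracy is stratified `cv_folds`-fold cross-validation with fold assignment
fixed by `cv_seed`, so every candidate subset in a run is scored on the same
partition — fitness differences between subsets are then differences in the
subsets, not in fold luck. Features are standardized to zero mean and unit
variance using training-fold statistics only. Classifier randomness (e.g.
KNN tie-breaking) runs in an RNG stream isolated from the swarm's, so
evaluation never perturbs the search trajectory and runs are reproducible
end-to-end from one seed.

For subsets wider than the training fold, the linear SVM is fitted through a
Cholesky factor of the linear Gram matrix: a linear SVM depends on the data
only through inner products, so training on an `n × n` factor `A` with
`A Aᵀ = Z Zᵀ` (and test rows `B` with `B Aᵀ = Z_te Z_trᵀ`) gives identical
predictions while capping the per-fit cost at `n` features. This is what
makes wrapper search affordable when the active pool reaches thousands of
features. A small ridge (`1e-8` of the mean Gram diagonal) keeps the factor
well-defined for rank-deficient subsets. Fitness values are cached by
selected-feature set; the cache is transparent (identical results with it
disabled, which is under test).

## The synthetic-data generator

`generate_dataset()` emulates the benchmark regime: `n_samples` ≤ ~200,
`n_features` up to ~6000, 2–4 classes. Informative features are Gaussian
with class means spaced `effect_size` within-class standard deviations apart
(random sign per feature so informative features are not mutually
collinear); redundant features are noisy copies (`redundancy_noise_sd`,
default 0.3) of randomly chosen informative features; irrelevant features
are standard normal, independent of the class. Class counts follow
largest-remainder apportionment, so requested proportions are met exactly.
`benchmark_shape_presets()` reproduces the (features × samples × classes) shapes
of four widely used public microarray benchmarks — 5966×102×2, 5748×171×4,
4434×50×4, 325×73×4 — with 30 informative and 20 redundant planted features.

The default generator settings (100 samples, 2000 features, 20 informative,
30 redundant, 2 classes, effect size 1.5) define the recovery conditions
used by the acceptance-level test: across 5 seeds, the grouped search is
expected to reach median cross-validated accuracy ≥ 0.90 with median subset
size ≤ 100 while drawing ≥ 70% of its selections from the planted set. The
Gaussian class-shift model was chosen over count-based (negative-binomial)
expression realism because it gives analytically controllable IG separation
between planted and noise features — which is exactly what recovery tests
need. What passing these tests does **not** show: robustness to heavy-tailed
or count-valued expression, batch effects, dropout, or correlated noise
structure between irrelevant features. Real-data behavior should be judged
on real data; the generator's role is to make the machinery falsifiable.

## The Friedman module

Selector comparisons across datasets use the Friedman test on an
algorithm × dataset score table. Each row is ranked (direction supplied per
row: accuracy rows higher-is-better, subset-size rows lower-is-better; ties
averaged), and

```
chi2_F = 12N / (k(k+1)) * (sum_j R_j^2 - k(k+1)^2 / 4)
F_F    = (N-1) chi2_F / (N(k-1) - chi2_F)
```

with `F_F` compared against the upper-alpha quantile of `F(k-1, (N-1)(k-1))`.
The chi-square is implemented in its classical uncorrected form; the tables
this test is typically applied to contain ties, so an optional
`tie_correction` flag (off by default) provides the standard correction
factor. The F form has a pole at `chi2 = N(k-1)` (perfect concordance);
the implementation raises an informative error there rather than returning
infinity. The bundled 8×13 score tables reproduce `chi2 = 75.43`,
`F = 25.67` (SVM) and `chi2 = 79.68` (KNN) — the latter is within 0.7% of
the published 80.19 for these tables; the residual reflects an unstated tie
convention in the source of those numbers, and the published F for the KNN
table (35.95) is not consistent with its own chi-square under the formula
above, which yields 34.17.

## Numerical and degenerate-input choices

- Group closure uses `cum >= I - 1e-12` so uniform-IG partitions are not
  off-by-one from accumulated rounding.
- An all-zero particle position is repaired at initialization by setting one
  uniformly chosen bit, and after a position update by setting the
  largest-velocity bit (deterministic, so repair does not consume RNG draws
  mid-iteration).
- pbest/gbest updates use strict improvement; on ties the earlier find wins,
  which keeps runs deterministic.
- A constant feature is one bin (IG 0, chi-square 0, Pearson 0 — not `NaN`).
- Labels are mapped to integer codes in first-appearance order; all outputs
  report original label strings.
- `filter_select()` counts a feature as informative iff its score is
  strictly positive; the selection size is `ceiling(n_informative / 2)`.

## Known limitations

- Grouping is contiguous on the IG ranking only; correlated features with
  similar IG land in the same group, and no between-feature redundancy
  measure (e.g. mutual information between features) informs the partition.
- The in-group objective is accuracy alone, so within a pool the swarm has
  no pressure toward smaller subsets; parsimony enters only through the
  out-group comparison across phases.
- Equal-width binning is sensitive to outliers in a feature's range;
  supervised discretization is deliberately out of scope.
- Wrapper accuracy estimated by CV on ≤ 200 samples has non-trivial
  variance; conclusions about selector superiority should rest on the
  cross-dataset Friedman comparison, not a single run.
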