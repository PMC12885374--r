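---
title: "Flea optimization with LASSO shrinkage: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flea optimization with LASSO shrinkage: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleaselect)
```

## The problem

Deep convolutional networks turn a histopathology image into a feature
vector, typically 2048 numbers from the penultimate pooling layer of a
residual network. Most of those coordinates are redundant or noisy for any
particular classification task, and downstream classifiers are both slower
and less accurate for it. `fleaselect` implements a hybrid feature
optimizer for this setting: a population-based metaheuristic (the flea
optimization algorithm, FOA) searches over feature-selection vectors, and
an L1-penalized least-squares criterion (LASSO) both scores candidate
subsets and performs the final shrinkage that zeroes out coefficients.
Everything is exercised on seeded synthetic feature data, so no external
image corpus is needed to test the machinery.

## The LASSO criterion

For a feature matrix $L \in \mathbb{R}^{N \times t}$, response $f$, and
penalty strength $\alpha \ge 0$, the objective is

$$J(\psi) = \frac{1}{2N}\lVert f - L\psi\rVert_2^2 + \alpha\lVert\psi\rVert_1 .$$

`fit_lasso()` minimizes $J$ by cyclic coordinate descent with the
soft-threshold update $\psi_j \leftarrow S(\rho_j, \alpha)$, implemented in
C++. Numerical choices:

* **Standardization.** Columns are z-scored with the *population* (1/N)
  standard deviation and the response is centered before descent; no
  intercept is fitted (centering absorbs it). Coefficients and the fit's
  objective are reported on this standardized scale, which is what makes a
  single default $\alpha = 0.0030$ meaningful across datasets.
  `lasso_objective()` by default evaluates the formula on the data exactly
  as passed (so hand-arithmetic on raw examples matches); pass
  `standardized = TRUE` to recompute a fit's objective.
* **Degenerate columns.** Exact-zero-variance columns are frozen at
  $\psi_j = 0$; with $\alpha = 0$ this is additionally warned about, since
  the coefficient is then genuinely unidentifiable.
* **Convergence.** A sweep ends the loop when the largest coefficient
  change drops below `tol` ($10^{-6}$ by default, at most 1000 sweeps).
  The objective is non-increasing across sweeps.
* **Multiclass responses.** Class labels are one-hot encoded and centered,
  one fit per class against a shared standardized design; the aggregate
  objective is the mean across classes, and a feature counts as selected
  when its coefficient is nonzero in *any* class fit. The encoding is a
  package choice — the reference usage applies the criterion to 8-class
  labels without stating one.

## The flea optimization algorithm

A population of $s$ fleas (default 20) lives in $[0,1]^t$; binarizing a
position at 0.5 yields a candidate feature mask. A mask's fitness is
$-J^\*$, the negated converged multiclass objective refit on the masked
columns only, so fitter fleas sit on masks with lower penalized loss. An
empty mask scores $-\infty$.

The update rule is this package's own construction: the source material
names the ingredients — exploration and exploitation, a "resilin"
elasticity drawn uniformly from (0, 1), an optimization learning rate of
$10^{-4}$, elitist fitness sorting — but does not print a legible update
equation. Per coordinate of every non-best flea:

* with probability `explore_probability` an **exploration jump**
  $f \leftarrow r u + (1 - r) f$, $u \sim U(0,1)$, with a fresh resilin
  draw $r$;
* otherwise an **exploitation move**
  $f \leftarrow f + r\,(\text{best} - f) + \eta\,\zeta$,
  $\zeta \sim N(0,1)$, $\eta = 10^{-4}$.

Positions are clipped to $[0,1]$; the incumbent best flea is never moved
(elitism), so the best-fitness trace is monotone non-decreasing by
construction. After the final generation, per-feature **importance** is the
mean position over the elite (top-fitness) half of the population, the
ranking sorts importance descending (ties broken by ascending index), and
the final mask is the nonzero set of a full-tolerance penalized fit on the
features whose importance reaches the binarization threshold.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 20 | fleas per generation |
| `max_iterations` | 690 | generations; the four magnification regimes map to 690/720/700/630 via `foa_iterations()` |
| `alpha` | 0.0030 | L1 penalty of the fitness and of the final shrinkage |
| `optimization_learning_rate` | 1e-4 | scale of the Gaussian drift in the exploitation move |
| `resilin_range` | (0, 1) | interval of the per-move jump elasticity |
| `explore_probability` | 0.02 | per-coordinate chance of an exploration jump |
| `binarize_threshold` | 0.5 | position-to-mask cut, also the importance cut |
| `fitness_max_sweeps` / `fitness_tol` | 100 / 1e-4 | capped in-loop solver budget; the final mask uses the full-tolerance solver |

`explore_probability` deserves a note: it was set by convergence
diagnostics, not taken from the source. At 0.10 a flea resamples ten
percent of its coordinates every generation, which keeps the elite
population too diffuse to concentrate within the ~700-generation budgets;
0.02 — the classic mutation-rate scale of evolutionary algorithms — let
every benchmark converge fastest, and is frozen as the default. The
in-loop solver tolerance ($10^{-4}$) is looser than the final fit's because
fitness only needs objectives accurate enough to *rank* masks.

Fitness evaluation is the hot path: the package precomputes the full
$(1/N)L^\top L$ Gram matrix and the class cross-products once per dataset,
slices the masked submatrix per evaluation in C++, and memoizes fitness by
mask (fleas revisit few distinct masks once the population concentrates).

## Synthetic feature data

`generate_features()` draws the world the tests live in:

* class centroids sit on a **scaled simplex** in the informative subspace
  — class $c$ at $(\text{sep}/\sqrt 2)\,e_c$ — giving pairwise centroid
  distance exactly `class_separation` whenever the informative dimension
  is at least the class count;
* informative columns are Gaussian around those centroids
  (`noise_sd`, default 1);
* redundant columns are $\rho$-correlated copies of cyclically chosen
  informative columns (`redundancy_rho`, default 0.9), built as
  $\rho z + \sqrt{1-\rho^2}\,\varepsilon$;
* all remaining columns are pure noise;
* rows are shuffled by the seed, and every output is a bit-identical
  function of spec + seed.

Defaults (8 classes, 2048 features) mirror the deep-feature regime the
method targets. What the generator does *not* emulate: histology texture,
stain variation, heavy-tailed or correlated noise, class imbalance, or any
nonlinear class boundary — a green recovery test establishes that the
machinery finds planted linear-Gaussian signal, not that it reproduces
performance on real tissue images.

The augmentation operators (`augment_image()`) apply, in order, rotation
uniform in ±5°, independent horizontal/vertical reflection at probability
0.5 each, per-axis shear uniform in ±0.05° (the shear bound is read as an
angle, matching its printed degree sign), and a bilinear resize to
224×224 with 3 channels; the order is a package choice, off-canvas pixels
are zero-filled.

The stratified splitter uses largest-remainder rounding so per-class train
counts sum exactly to `round(fraction * n)`; singleton classes are an
error (naming the class) rather than silently unsplittable.

## Dissimilarity statistics

`dissimilarity_report()` computes, per class, the mean Euclidean distance
among its samples (intra-class, over unordered pairs, self-pairs excluded),
the mean distance to all other-class samples (inter-class, over ordered
cross pairs), and the class margin inter − intra. Singleton classes yield
`NA` with a warning — zero would fake perfect compactness. When invoked
after selection, distances are computed on the selected subspace.

## Performance metrics

`compute_metrics()` evaluates the standard confusion-table suite —
accuracy, error, sensitivity/recall, specificity, precision, false
positive rate, F1, MCC and Cohen's kappa (from observed and expected
agreement) — with every zero denominator mapped to a typed `NA`, never an
exception. Multiclass scalars are **macro** averages of one-vs-rest
metrics (accuracy/error computed globally), reproducing
single-number-per-classifier reporting without class weighting
assumptions. The one-sample t kernel and the t-based confidence interval
round out the suite; with six accuracy values the reference usage is
$df = 5$.

## Architecture census

`build_standard_resnet50()` and `build_modified_resnet50()` construct
typed layer DAGs under one block grammar: a 7×7/64 stem with batchnorm,
ReLU and max-pool; bottleneck stages of 1×1–3×3–1×1 convolutions (each
conv followed by batchnorm, ReLU after the first two and after the
residual addition); a 1×1 projection with batchnorm on each stage's first
shortcut; then global average pool, fully-connected head and softmax. The
standard graph uses stage configuration (3, 4, 6, 3), a 1000-way head and
a terminal classification node — 177 nodes; the slimmed variant uses
(3, 4, 3, 3), an 8-way head and no classification node — 146 nodes. The
stage configuration (3, 4, 3, 3) realizes the 13 addition layers of the
slimmed inventory; the source never prints its block layout, and this is
the only four-stage layout under which both totals reproduce together
with the per-kind counts.

Parameters: convolutions are bias-free ($k^2 \cdot c_{in} \cdot c_{out}$;
batchnorm follows every convolution and absorbs the bias — the convention
required to land on the printed 25.6 M), batchnorm carries scale and
offset, the head carries weights and bias. The standard graph counts
25,557,032 learnable parameters. The slimmed network's printed 16.8 M is
**not** reproduced by any default here: the filter-width reductions behind
it are never enumerated in the source (whose own prose is inconsistent
about the starting count), so `width_multiplier` is exposed for users to
explore width schedules, and no default claims 16.8 M.

## Pipeline and classifier bank

`run_pipeline()` chains: cross-validated evaluation of the classifier bank
on the full space → FOA selection → re-evaluation on the selected subspace
→ percent-improvement table and the class-dissimilarity report on selected
features. Cross-validation is stratified k-fold (default 10); the 70/30
stratified split is reserved for split-based stages such as the ablation's
held-out regressor, resolving the simultaneous appearance of both
protocols in the source. The bank — a CART-style Gini decision tree and
five multilayer perceptrons with hidden layouts (10), (20), (50),
(10, 10), (10, 10, 10), tanh hidden units, softmax outputs, full-batch
gradient descent with momentum — is implemented in-package because the
runtime environment ships neither a tree nor a neural-network package; it
mirrors the reference study's MATLAB classifiers in spirit, not
bit-for-bit. Training time is reported but excluded from all acceptance
checks (hardware-dependent).

`run_ablation()` compares three arms on one seed: shrinkage-only,
search-only (importance threshold without the final shrinkage), and the
hybrid, each reporting selected count, the held-out MSE of a shared
least-squares one-hot regressor, a convergence-iteration count and a
final-gradient analogue.

## Known limitations, and one deliberately red check

* **The superiority property is not reproducible at desk scale.** The
  acceptance suite asserts, as specified, that mean planted-feature recall
  of the full search is at least that of plain shrinkage at the same
  $\alpha$ on redundant-block data. Measured on the frozen benchmark
  (80×64, 8 informative originals plus 16 copies at $\rho = 0.95$,
  $\alpha = 0.0030$, 690 generations, 10 seeds), plain LASSO sits at the
  recall ceiling of 1.0 — at this penalty on $n > p$ data it selects
  essentially every feature — while the search converges to the same full
  candidate set but occasionally loses one original whose correlated
  copies cover it, averaging 0.9875. The check can therefore at best tie
  and stays red. The structural reason: with the training objective as
  fitness, adding columns (almost) never hurts, so the search's fixed
  point is the plain shrinkage selection; a fitness with held-out error or
  an explicit cardinality penalty would be needed for a genuine advantage,
  and neither is part of the specified objective.
* The in-suite end-to-end pipeline run uses a reduced search budget (15
  generations on the 2048-wide dataset) purely for runtime; the asserted
  properties (selection below 2048, paired tables, reproducibility) are
  budget-independent.
* Importance averaging over the elite half, and the iteration-to-regime
  mapping 690/720/700/630 → 40×/100×/200×/400× (printed comma-separated,
  unlabeled), are package interpretations.
* Selection quality degrades gracefully, not catastrophically: the
  paired-evaluation test asserts only that selection costs at most 0.02
  mean accuracy on planted-signal data.
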