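---
title: "Scoring and integrating quantitative genetic interaction screens with QMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and integrating quantitative genetic interaction screens with QMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmascreen)
```

## The problem

Large-scale genetic interaction screens cross a collection of *query*
mutants against a collection of *array* mutants and measure the fitness of
every double mutant, giving an `m x n` matrix `W` with entries `w[a, b]`.
Under the classical multiplicative null model, two non-interacting
mutations combine as the product of their single-mutant fitness effects,

```
w[a, b] = w_a * w_b,
```

so the matrix of non-interacting pairs is approximately rank one,
`W ~ x %o% y`, with `x` the query-side and `y` the array-side single-mutant
fitness vectors. A genetic interaction is a deviation from this
expectation: the interaction score is the residual

```
s[a, b] = w[a, b] - s(x[a], y[b]),
```

positive for alleviating (positive) interactions, negative for aggravating
ones, with synthetic lethality (`w[a, b] = 0`) the extreme negative case.
Many screens never measure single mutants directly, so `x` and `y` must be
estimated from `W` itself — robustly, because the interactions we want to
detect are exactly the cells that violate the model.

## Quantile-based matrix approximation

`qma_estimate()` is a multiplicative analogue of Tukey's median polish
with quantiles in place of medians. It initializes `x[a]` as the
`p`-quantile of the present values in row `a`, computes `y[b]` as the
`q`-quantile of the ratios `w[a, b] / x[a]` down column `b`, and then
alternates row quantiles of `w / y` and column quantiles of `w / x` until
the maximum relative change of the concatenated `(x, y)` drops below `tol`
or `max_iter` sweeps have run. With `max_iter = 1` the procedure reduces to
the plain two-pass row-then-column quantile estimate; further sweeps refine
it and converge to a fixed point of the alternation. Any strictly positive
rank-one matrix is an exact fixed point after the first sweep, for every
`(p, q)` — this is the central correctness invariant and is enforced by the
test suite at `1e-10`.

Three conventions deserve mention:

* **Gauge.** The decomposition is identifiable only up to `x -> c x`,
  `y -> y / c`. We anchor `x` in the fitness units of `W` through its
  initialization from raw row quantiles; `y`, built from ratios, then sits
  on the fitness scale too for screens normalized to median ≈ 1. No
  post-hoc rescaling is applied, so results are deterministic and the
  minimum/maximum scoring functions (which are gauge-dependent) have a
  well-defined meaning.
* **Orientation.** `x` is bound to rows (queries) and `y` to columns
  (arrays) throughout the package; descriptions of this family of methods
  sometimes swap the two words, so the binding is stated here once and used
  consistently.
* **Quantile definition.** Linear interpolation between order statistics
  (`stats::quantile()` type 7). Any convention satisfies the invariants;
  one must be pinned for reproducible tests.

Numerical safeguards: estimates below a positivity floor of `1e-8` are
excluded from ratio denominators (a lethal query would otherwise divide by
zero), and a strain whose estimate collapses entirely is pinned at the
floor; rows or columns with fewer than `min_obs` (default 5) usable
observations get `NA` estimates, because quantiles of tiny samples are
unstable, and every score depending on them is undefined.

Defaults are `p = q = 0.5` (the median baseline; `median_baseline_score()`
is exactly the single-sweep median fit with product scoring),
`max_iter = 20` and `tol = 1e-6`. On noisy screens the alternation
typically shrinks its updates geometrically; reaching `max_iter` before
`tol` leaves estimates stable to about `1e-5`, which is far below the noise
level of any real screen. Per-dataset tuned `(p, q)` settings are deliberate
user configuration, not defaults.

## Scoring functions and extreme calls

`score_interactions()` supports four null/scoring functions: `product`
(the multiplicative model), `minimum` and `maximum` (masking-style
alternatives), and `scaled_epistasis`, which divides the product residual
by a sign-dependent normalizer — the distance from the expectation to the
masking bound `min(x[a], y[b])` for positive residuals, and the distance to
lethality (`x[a] * y[b]`) for negative ones, floored at `1e-8`. The scaled
variant is a convention of this package, consistent with the scaled
epistasis measures used for high-resolution symmetric data.

`call_extremes()` returns the pairs at or above the `1 - f` quantile and at
or below the `f` quantile of the defined scores, with `f = 0.03` per tail
by default, following the empirical ~3% interaction-rate estimate from
unbiased screens. Boundary ties are included; a pair falling in *both*
tails (possible only when the thresholds coincide, e.g. constant scores) is
ambiguous and dropped from both, so degenerate inputs yield no calls. The
3% is applied per tail here; treating it as a combined two-tail budget is a
legitimate alternative reading, and the `tail_fraction` argument makes
either choice explicit.

## Reference interaction classes

`build_class_matrix()` turns a curated edge list into a ternary
(interacting / non-interacting / excluded) matrix per interaction class.
Gene pairs are unordered, so an A–B edge also labels B–A; pairs annotated
in both the positive and negative class are ambiguous and excluded from
both; pairs from the screens under evaluation can be excluded via
`exclude_edges` (also unordered); and self pairs are always excluded, since
a cell whose query and array are the same gene measures a single mutant.
Category terms are matched case-insensitively after trimming and both
"Synthetic Lethality" and "Synthetic Lethal" spellings are accepted, since
database exports vary.

## Comparing and integrating screens

`intersect_datasets()` matches shared pairs oriented (query-to-query,
array-to-array) by default; transposed matching is an opt-in for symmetric
screens, with the two orientations averaged when both are present — the
same convention as duplicate-strain merging. `correlations()` reports
Pearson and Spearman over complete cases and flags (rather than throws on)
degenerate inputs. `extreme_agreement_auc()` asks how well one screen's
scores rank the other's extreme tail, summarized as a ROC AUC, and
`enrichment_grid()` overlays a rank-rank scatter with equal-count bins and
upper-tail hypergeometric p-values per cell, clamped to `[1e-100, 0.99]`
for display. Equal-count (rank-quantile) bin boundaries are used because
the underlying plot is a rank scatter; ties on a boundary go to the lower
bin.

For integration, `rank_pairs()` ranks the shared pairs within each screen
(rank 1 = strongest evidence in the chosen direction, average ranks on
ties) and `aggregate_ranks()` combines two or more rankings by the minimum,
maximum, product, or Borda count (sum) of the ranks. Ranks are computed
within the common intersection, not on the full matrices, so the rank
scales are comparable; final orderings break ties lexicographically by pair
identifier so output files are reproducible.

## ROC evaluation

`roc_curve()` builds the step curve with tied scores collapsed into single
thresholds (diagonal segments), which makes the trapezoidal AUC equal the
Mann–Whitney concordance statistic with ties counted one half — the test
suite verifies this equivalence against brute-force pair counting.
`partial_auc()` integrates over FPR in `[0, r]` (linear interpolation at
`r`) and normalizes by `r`, so the chance level is `r / 2` (0.050 at
`r = 0.1`); `early_sensitivity()` reads the TPR at the largest achieved FPR
at or below the cut (default 0.01) without interpolation — with fewer than
`1 / fpr0` negatives the cut is unreachable and the conservative TPR at
FPR 0 is reported. A uniform random classifier calibrates to AUC 0.500,
normalized pAUC 0.050 and early sensitivity 0.010, which the acceptance
checks recompute by simulation.

## The synthetic screen generator

Real screens of this kind cannot be bundled, so `simulate_screen()`
generates screens whose structure mirrors the modelling assumptions:

* single-mutant fitness ~ Normal(1.0, 0.15) truncated to `[0.05, 1.5]`,
  giving a median near 1 as in median-normalized screens;
* non-interacting cells exactly `x[a] * y[b]` before noise;
* 1.5% of pairs planted as positive interactions
  (`w -> gamma * x[a] * y[b]`, `gamma ~ U(1.3, 2)`) and 1.5% as negative
  (`gamma ~ U(0, 0.6)`, 30% of them fully lethal), totalling the ~3%
  empirical interaction rate;
* multiplicative log-normal noise (`sd = 0.1` on the log scale), chosen so
  that recovery of the generating vectors is demanding but achievable —
  rank correlations between estimated and true single-mutant fitness
  exceed 0.95 at these settings, the same regime reported for model-based
  estimates against measured single mutants on real data;
* 5% of cells missing completely at random, and 2% of strains duplicated
  with independent noise, so duplicate merging is exercised.

Because the planted effects are multiplicative, the sign of each planted
pair's product residual is analytically known, which the tests use. One
global seed drives hierarchically derived per-stage seeds, and
`simulate_replicate_pair()` reuses the truth stage while redrawing the
noise stages, emulating two platforms assaying the same genetic network.

What the generator does **not** model: batch and plate spatial effects,
linkage (same-chromosome) artifacts, strain-specific biases, or
non-multiplicative noise — all upstream preprocessing concerns of real
screening platforms. Passing tests on these synthetics therefore
demonstrate correctness of the estimation and evaluation machinery under
the multiplicative model, not robustness to every artifact of a particular
platform.

## Problem sizes in the tests

The test suite uses 200 × 100 screens (the generator default) for recovery
and detection checks, 50 replicate pairs for the integration benefit
check, 1000 replicates for random-classifier calibration, 200 random
instances for the AUC/concordance equivalence, and exhaustive enumeration
up to a universe of 12 for the hypergeometric oracle — sizes at which the
Monte-Carlo error is well below the margins being asserted while the whole
suite stays fast.

## Known limitations

* Only rank-one structure is modelled; screens with strong secondary
  structure (e.g. batch effects) should be corrected upstream.
* The alternating quantile iteration has no general convergence guarantee;
  `max_iter` bounds the work and the reported `converged` flag tells you
  which stopping rule fired.
* `minimum`/`maximum` scoring depends on the gauge described above; compare
  such scores only between fits produced with the same convention.
* Reference classes treat every curated edge equally; no per-publication
  evidence weighting is attempted.
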