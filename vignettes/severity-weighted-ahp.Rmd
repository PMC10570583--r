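---
title: "Severity-weighted AHP risk ranking: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-weighted AHP risk ranking: models, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcrisk)
```

## The problem

Ranking injury-risk factors from surveillance statistics runs into two
difficulties. First, raw incident counts ignore severity: property-damage
crashes vastly outnumber fatal ones, so unweighted counts understate the
factors that kill. Second, surveillance tables rarely cover every cell an
analyst needs, so some judgments must remain expert-supplied. This package
implements a semi-quantitative middle road: incident statistics are weighted
by the *cost* of their consequences and drive most of the pairwise
judgments, while the top of the criteria hierarchy stays qualitative.

The machinery is the analytic hierarchy process (AHP): factors are arranged
under criteria, pairwise comparison matrices (PCMs) encode relative
importance on Saaty's 1–9 scale, priority weights are the principal
eigenvector of each matrix, a consistency ratio guards against incoherent
judgments, and local weights multiply up the hierarchy into a global
ranking.

## Severity cost factors

Each severity class (e.g. fatal / injury / property-only crashes) gets an
integer **cost factor**: its average per-event cost divided by the cost of
the reference class, rounded half-up, floored at 1. For the packaged US-2019
case study: \$1,565,000 / \$4,711 → 332 for fatal crashes, \$20,235 /
\$4,711 → 4 for injury crashes, 1 for property damage. Annual counts times
cost factors, normalized to unit sum, give the **normalized severity
factors** — the share of total crash cost carried by each class (0.470 /
0.326 / 0.204 here). These factors are scale-invariant in the currency (only
cost *ratios* matter) and strictly monotone in the counts.

Per-factor evidence shares are multiplied by these severity factors
(`weighted_share()`), and summing a factor's weighted shares over the
severity classes yields its **importance score** in percent
(`importance_scores()`). Scores deliberately need not sum to 100 within a
criterion group: they are shares of class totals attributable to a factor,
not a partition.

## From scores to Saaty matrices

The ratio of two importance scores is a continuous quantity; a PCM entry is
a Saaty intensity in {1/9, …, 1/2, 1, 2, …, 9}. The quantizer maps a ratio
r ≥ 1 to `floor(r)`, bumped up by one when the fractional part reaches the
`ceil_threshold`, clamped to [1, 9]; ratios below one map to the reciprocal
of the quantized inverse, so reciprocity holds by construction. Ratios this
large or larger than 9 saturate at 9 — the scale's deliberate ceiling.

The threshold default is 0.25. The mapping from score ratios to intensities
is inherently a judgment call — it is exactly where expert discretion enters
a semi-quantitative method — and 0.25 is the simplest one-parameter rule
that reproduces every sub-criteria matrix of the packaged case study from
its printed score sums (including the borderline cases 1.36 → 2 and
1.12 → 1). It is configurable, and an explicit override map
(`saaty_quantizer(overrides = ...)`) expresses expert dissent cell by cell;
overrides are applied last and force the reciprocal cell too. Whether the
case study's authors used a threshold rule or purely judgmental rounding is
not knowable from the published tables; the default merely reproduces them.

The criteria-level matrix cannot be derived from the evidence tables — the
top level is judged semi-qualitatively — so the hierarchy config carries it
as an expert-supplied inline matrix.

## Weighting and the two lambda-max conventions

`ahp_weights()` defaults to the principal eigenvector computed by power
iteration from the uniform vector, sum-normalized each step, stopping when
the largest component change drops below `tol` (default 1e-12, cap 10,000
iterations; positive matrices always converge by Perron–Frobenius, and the
iteration count is tiny at these orders). The classical approximation —
row means of the column-normalized matrix — is exposed as
`method = "rowmean"`; for matrices passing the consistency check the two
agree to a few parts in a thousand.

Saaty's estimator `lambda_max = mean_i (Aw)_i / w_i` equals the matrix order
n exactly on consistent matrices and exceeds it otherwise. Consistency is
summarized by CI = (λmax − n)/(n − 1) and CR = CI/RI(n) with Saaty's random
indices (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41 for n ≤ 8; the standard
extension to n = 9, 10 sits behind `extended = TRUE` since the core table
stops at 8). A matrix passes when CR < 0.10; at n ≤ 2 no inconsistency is
possible and CR is defined as 0.

`pcm_consistency()` supports two conventions, and the distinction matters at
the fourth decimal:

* `"rowmean"` (default): the estimator is evaluated at the full-precision
  row-mean weights and rounded to 4 decimals before CI/CR are formed. This
  is the classical hand calculation, and it reproduces the case study's
  printed diagnostics exactly — λmax 3.0055 / 4.0042 / 3.0537 and CR
  0.004741 / 0.046293.
* `"eigen"`: the estimator at the eigenvector equals the principal
  eigenvalue itself, reported unrounded. This is the mathematically exact
  quantity; it differs from the row-mean figures only in the fourth decimal
  (e.g. 3.053622 vs 3.0537 for the driver-behavior matrix).

Published AHP tables commonly mix the two (the case study's local weights
match the eigenvector while its diagnostics match the row-mean estimator),
which is why both are first-class here and every report records which was
used. Ranking weights always come from the method the user chose; the
convention only affects the diagnostic.

## Synthesis, ranking, ties

Global leaf weights are local weights times the parent criterion weight;
when every level is unit-sum the globals are too (checked, tolerance 1e-6 on
input sums). Ranking is competition style ("1224"): weights are rounded to
`tie_decimals` (default 3) first, equal rounded weights share the smallest
applicable rank and are flagged, and the next rank is skipped. Rounding
before tie detection is deliberate: a three-decimal report that shows two
factors at 0.024 should not silently order them by invisible digits. Ties
are broken for *display order* only, alphabetically, which keeps the
ranking invariant under leaf relabeling.

## BWM and FUCOM comparators

Two alternative weight-elicitation methods are included so a ranking can be
cross-checked against methods with different elicitation structure:

* **Best-worst method**: minimize ξ subject to |w_B/w_j − a_Bj| ≤ ξ and
  |w_j/w_W − a_jW| ≤ ξ over the weight simplex (the original nonlinear
  formulation — ranks, not interval weights, are what gets compared).
* **FUCOM**: minimize χ subject to |w_k/w_{k+1} − φ_k| ≤ χ and
  |w_k/w_{k+2} − φ_k φ_{k+1}| ≤ χ for chained comparative priorities φ.

Both are nonsmooth min-max programs solved by multi-start Nelder–Mead over
log-weights (softmax parametrization keeps the iterate strictly inside the
simplex). Starts include the uniform vector, the consistent candidates
obtained by inverting each comparison vector (exact when the input is
consistent, so ξ = χ = 0 is found without search), and a fixed list of
seeded jitters; the caller's RNG stream is saved and restored. A second
Nelder–Mead pass from the first optimum polishes nonsmooth corners. The
deviations ξ and χ are zero exactly on consistent inputs, and test oracles
(dense simplex grid search refined to a 1e-3 step) bound the solver's
optimality gap. One caveat surfaced by those oracles: for some inconsistent
inputs the min-max optimum is nearly flat, so the *arg-min* is only
determined to the flatness scale even when the attained deviation is tight.

How to feed the comparators is genuinely open — the comparison they
replicate does not publish its input vectors. The package derives them from
the same severity-weighted evidence: at the sub-criteria level, best/worst
are the extreme importance scores and the vectors are quantized score ratios
(same quantizer as the PCMs); at the criteria level, where only the expert
matrix exists, the BWM vectors are the best criterion's row and the worst
criterion's column and the FUCOM priorities are the consecutive entries
along the expert ordering. This is one plausible reading, and it is why only
rank agreement — not weight decimals — is asserted against the published
comparison (all three methods put DUI first and weather last on the packaged
study).

## Synthetic matrices

`generate_pcm()` draws a ground-truth weight vector from a symmetric
Dirichlet, forms the consistent ratio matrix, and perturbs the upper
triangle by log-normal factors exp(ε), ε ~ N(0, σ²), mirroring ε on the
lower triangle. This perturbation is chosen because it preserves positivity
and reciprocity *exactly* while degrading cardinal consistency smoothly with
σ, so σ calibrates realism: σ = 0 gives CR = 0 and exact parameter recovery;
σ ≈ 0.05 keeps essentially all 4×4 matrices under CR 0.10; CR grows
monotonically in σ in expectation. All randomness flows through the spec's
single integer seed. What the generator does **not** emulate: systematic
judgment biases (anchoring, scale compression), expert disagreement, or the
discreteness of real elicited judgments unless `quantize = TRUE` — so
passing recovery tests show the solvers are correct, not that real expert
matrices are this well behaved.

Problem sizes used in the test suite — orders 2–8, ~100 seeds for recovery,
60–100 replicates per noise level — were chosen as the smallest sets that
exercise every matrix order and give stable Monte-Carlo proportions.

## Numerical choices and degenerate inputs

* Cost factors round half-up (`floor(x + 0.5)`), not banker's rounding, and
  floor at 1; presentation rounding (3 decimals for weights, 4 for λmax, 6
  for CR, 1 for percents) happens only at report time, never internally.
* Thousands separators in CSV inputs (commas, apostrophes, Unicode primes)
  are stripped on read; output is plain ASCII decimals.
* Matrices above 9×9 are rejected by default (the Saaty scale stops at 9)
  with an explicit `allow_large` escape hatch.
* Degenerate cases: an all-zero count schema raises a degenerate-schema
  error; a zero importance score raises a division error naming the factor;
  a single-criterion or single-leaf study short-circuits to weight 1 rather
  than building an impossible 1×1 matrix.
* PCM validation is report-based (`validate_pcm()` lists every violated
  invariant with indices) so a config author sees all problems at once.

## Known limitations

* Cost factors are point estimates; no uncertainty propagation or
  multi-year inflation adjustment is attempted.
* Evidence shares are consumed as given; the package does not reconstruct
  them from raw surveillance records.
* Group decision-making (aggregating multiple experts) and fuzzy/interval
  extensions are out of scope.
* The quantizer threshold and the comparator-input derivation are documented
  conventions, not identified quantities; sensitivity to them is exposed via
  `ceil_threshold` and the override map rather than estimated.
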