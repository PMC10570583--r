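# smcrisk

Severity-weighted multi-criteria risk ranking with the analytic hierarchy
process (AHP), for risk analysts who want their pairwise judgments anchored
in surveillance statistics instead of surveys.

Classical AHP elicits every pairwise comparison from experts, which makes
risk rankings as subjective as the panel behind them. `smcrisk` implements a
semi-quantitative alternative: incident counts per severity class are
weighted by integer **severity cost factors** (how much costlier a fatal or
injury event is than a property-damage-only one), per-factor evidence shares
are weighted by the resulting normalized severity factors and summed into
**importance scores**, and the score ratios are quantized onto the Saaty 1–9
scale to build the sub-criteria pairwise comparison matrices. Only the top,
criteria-level matrix remains expert-supplied.

The core quantities, in the field's standard notation:

- PCM: positive reciprocal matrix `A`, `a_ij ≈ w_i / w_j`, `a_ji = 1/a_ij`
- weights: principal eigenvector, `A w = λmax w` (power iteration; the
  classical row-mean approximation is also available)
- consistency: `CI = (λmax − n)/(n − 1)`, `CR = CI / RI(n)`, accepted when
  `CR < 0.10`
- synthesis: `global(leaf) = local(leaf) × weight(parent)`, ranked with
  competition (tie-aware) ranks

Best-worst method (BWM, min-max deviation from best-to-others and
others-to-worst vectors) and full consistency method (FUCOM, chained
comparative priorities) solvers are included so a ranking can be
cross-checked across elicitation schemes, plus a seeded generator of
synthetic PCMs with controlled consistency for simulation work.

## Worked example: US driving risks, 2019

The packaged case study ranks nine driving-risk factors (weather, light,
road design, control devices, DUI, non-performance errors, decision errors,
performance errors, recognition errors) under three criteria (environment,
driver state, driver behavior) from 2019 US crash statistics.

```r
library(smcrisk)
fx <- us2019_fixture()
fx$schema
#> Severity schema (reference: Minor )
#>  class consequence avg_cost   count cost_factor weighted normalized
#>  Fatal       Fatal  1565000   33244         332 11037008      0.470
#>  Major      Injury    20235 1916000           4  7664000      0.326
#>  Minor    Property     4711 4806000           1  4806000      0.204
```

Fatal crashes are 332 times costlier than property-only ones
(\$1,565,000 / \$4,711); cost-weighting the annual counts shows fatal
crashes carrying 47.0 % of total crash cost despite being the rarest class.
Running the full pipeline — severity weighting, score aggregation, matrix
quantization, eigenvector weighting, consistency checks, synthesis,
ranking:

```r
rep <- run_pipeline(study_config(fx$schema, fx$evidence, fx$hierarchy))
rep$consistency$C3   # driver-behavior matrix diagnostic
#> n = 3  lambda_max = 3.0537  CI = 0.0269  RI = 0.58  CR = 0.046293  [consistent, CR < 0.10]
rep$ranking
#>  label weight percent rank
#>     R5  0.390    39 %    1
#>     R7  0.230    23 %    2
#>     R9  0.145    14 %    3
#>     R8  0.091     9 %    4
#>     R3  0.045     5 %    5
#>     R6  0.043     4 %    6
#>     R2  0.024     2 %   7*
#>     R4  0.024     2 %   7*
#>     R1  0.008     1 %    9
#> (* same ranking level)
```

Driving under the influence (R5) dominates with 39 % of global weight,
followed by decision errors such as speeding (23 %) and recognition errors
such as distracted driving (14 %); light and control devices tie at rank 7.
Every matrix passes the CR < 0.10 consistency check. The same study can be
re-weighted with BWM and FUCOM:

```r
cmp <- compare_methods(study_config(fx$schema, fx$evidence, fx$hierarchy))
cmp$ranks   # all three methods agree: R5 first, R1 (weather) last
```

See `vignettes/severity-weighted-ahp.Rmd` for the models, the quantizer and
consistency conventions, and known limitations.

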