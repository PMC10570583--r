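Package: smcrisk
Title: Semi-Quantitative Multi-Criteria Risk Ranking with Severity-Weighted AHP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks risk factors by combining incident surveillance statistics
    with severity cost weighting inside an analytic hierarchy process (AHP).
    Severity classes are converted to integer cost factors, incident counts are
    cost-weighted and normalized into severity factors, per-factor evidence
    shares are aggregated into importance scores, and pairwise comparison
    matrices are quantized onto the Saaty 1-9 scale from score ratios.
    Criteria and sub-criteria are weighted by the principal-eigenvector method
    with consistency-ratio checking, synthesized into global weights, and
    ranked with competition (tie-aware) ranks. Best-worst method (BWM) and
    full consistency method (FUCOM) solvers are included for method
    comparison, together with a synthetic pairwise-matrix generator with
    controlled consistency for simulation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
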