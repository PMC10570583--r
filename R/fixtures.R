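# Packaged US-2019 road-risk case study and a synthetic PCM generator with
# controlled consistency for property tests and simulations.

#' The US 2019 driving-risk case study
#'
#' Loads the packaged case-study inputs: the three-class severity schema
#' (fatal / injury / property-damage crash counts and per-event costs), the
#' severity-weighted evidence tables for the environment, driver-state, and
#' driver-behavior criterion groups, and the three-criteria, nine-factor
#' hierarchy with its expert-supplied criteria-level comparison matrix.
#'
#' @return List with elements `schema` (normalized [severity_schema()]),
#'   `evidence` (named list of [evidence_table()]), and `hierarchy` (parsed
#'   hierarchy config; see [read_hierarchy_config()]).
#' @export
us2019_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "smcrisk",
                                 mustWork = TRUE)
  schema <- read_severity_csv(ext("us2019_severity.csv"),
                              reference = "Minor")
  evidence <- read_evidence_csv(ext("us2019_evidence.csv"))
  hierarchy <- read_hierarchy_config(ext("us2019_hierarchy.yaml"))
  list(schema = schema, evidence = evidence, hierarchy = hierarchy)
}

#' Specification for a synthetic pairwise comparison matrix
#'
#' @param n Number of factors (>= 2).
#' @param concentration Dirichlet concentration for the ground-truth weight
#'   draw; 1 gives a uniform draw on the simplex.
#' @param noise_sigma Standard deviation of the multiplicative log-normal
#'   perturbation applied to each upper-triangle ratio; 0 gives a perfectly
#'   consistent matrix.
#' @param quantize Snap the perturbed ratios onto the Saaty scale?
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, concentration = 1, noise_sigma = 0,
                           quantize = FALSE, seed = 1L) {
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (concentration <= 0) stop("`concentration` must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), concentration = concentration,
                 noise_sigma = noise_sigma, quantize = isTRUE(quantize),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic PCM with known ground truth
#'
#' Draws a ground-truth weight vector `w` from a symmetric Dirichlet, forms
#' the consistent ratio matrix `w_i / w_j`, and perturbs each
#' upper-triangle entry by a log-normal factor `exp(eps_ij)` with
#' `eps_ij ~ N(0, sigma^2)`; the lower triangle is filled with reciprocals,
#' so positivity and reciprocity hold exactly while cardinal consistency
#' degrades smoothly with `sigma`. Optionally the perturbed ratios are
#' quantized onto the Saaty scale. Deterministic under the spec's seed; the
#' caller's RNG stream is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `weights` (the ground truth, named) and `pcm`.
#' @export
generate_pcm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  n <- spec$n
  g <- stats::rgamma(n, shape = spec$concentration)
  w <- g / sum(g)
  labels <- paste0("F", seq_len(n))
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- (w[i] / w[j]) * exp(stats::rnorm(1, sd = spec$noise_sigma))
    if (spec$quantize) r <- quantize_to_saaty(r)
    m[i, j] <- r
    m[j, i] <- 1 / r
  }
  list(weights = stats::setNames(w, labels),
       pcm = pcm(m, labels, allow_large = n > 9))
}

#' Consistency-ratio simulation over synthetic PCMs
#'
#' Generates `replicates` perturbed matrices at a given order and noise
#' level (seeds `seed, seed + 1, ...`) and records each consistency ratio.
#'
#' @param n Matrix order.
#' @param sigma Log-normal noise standard deviation.
#' @param replicates Number of matrices.
#' @param seed Base seed.
#' @param quantize Passed to [synthetic_spec()].
#' @return Data frame with columns `seed`, `cr`, `lambda_max`.
#' @export
simulate_cr <- function(n, sigma, replicates = 100L, seed = 1L,
                        quantize = FALSE) {
  rows <- lapply(seq_len(replicates), function(k) {
    sp <- synthetic_spec(n, noise_sigma = sigma, quantize = quantize,
                         seed = seed + k - 1L)
    gp <- generate_pcm(sp)
    rep <- pcm_consistency(gp$pcm, lambda_convention = "eigen")
    data.frame(seed = sp$seed, cr = rep$cr, lambda_max = rep$lambda_max)
  })
  do.call(rbind, rows)
}
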