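# Best-worst method (BWM) and full consistency method (FUCOM) weight
# solvers, used as comparators for the AHP-based ranking. Both share the
# severity-weighted evidence front-end: their comparison vectors are derived
# from the same importance scores that feed the pairwise matrices.

#' BWM input vectors
#'
#' @param labels Factor labels.
#' @param best,worst Indices (or labels) of the best and worst factor.
#' @param best_to_others Comparison vector `a_Bj` (best over others);
#'   `a_BB` must be 1.
#' @param others_to_worst Comparison vector `a_jW` (others over worst);
#'   `a_WW` must be 1.
#' @return An object of class `bwm_input`.
#' @export
bwm_input <- function(labels, best, worst, best_to_others, others_to_worst) {
  n <- length(labels)
  if (is.character(best)) best <- match(best, labels)
  if (is.character(worst)) worst <- match(worst, labels)
  stopifnot(length(best_to_others) == n, length(others_to_worst) == n,
            best %in% seq_len(n), worst %in% seq_len(n))
  if (any(best_to_others < 1) || any(others_to_worst < 1))
    stop("comparison intensities must be >= 1", call. = FALSE)
  if (abs(best_to_others[best] - 1) > 1e-9)
    stop("best_to_others[best] must be 1", call. = FALSE)
  if (abs(others_to_worst[worst] - 1) > 1e-9)
    stop("others_to_worst[worst] must be 1", call. = FALSE)
  if (best_to_others[worst] < max(best_to_others) - 1e-9)
    stop("best_to_others[worst] must be the largest entry", call. = FALSE)
  structure(list(labels = labels, best = best, worst = worst,
                 best_to_others = as.numeric(best_to_others),
                 others_to_worst = as.numeric(others_to_worst)),
            class = "bwm_input")
}

#' FUCOM input: ranked factors with comparative priorities
#'
#' @param labels Factor labels ordered from most to least significant.
#' @param priorities Vector of `n - 1` comparative priorities
#'   `phi(k/k+1) >= 1`, the judged ratio between consecutively ranked
#'   factors.
#' @return An object of class `fucom_input`.
#' @export
fucom_input <- function(labels, priorities) {
  n <- length(labels)
  stopifnot(n >= 2, length(priorities) == n - 1)
  if (any(priorities < 1))
    stop("comparative priorities must be >= 1 (labels are ranked by ",
         "decreasing significance)", call. = FALSE)
  structure(list(labels = labels, priorities = as.numeric(priorities)),
            class = "fucom_input")
}

#' Derive BWM and FUCOM inputs from importance scores
#'
#' The best (worst) factor is the one with the highest (lowest) score, ties
#' broken by label order with a warning. Comparison vectors and comparative
#' priorities are the corresponding score ratios, quantized with the same
#' Saaty quantizer used for the pairwise matrices (or left raw when
#' `q = NULL`).
#'
#' @param scores Named vector of positive importance scores.
#' @param q A [saaty_quantizer()], or `NULL` for unquantized ratios.
#' @return List with elements `bwm` ([bwm_input()]) and `fucom`
#'   ([fucom_input()]).
#' @export
derive_comparator_inputs <- function(scores, q = saaty_quantizer()) {
  labels <- names(scores)
  if (is.null(labels)) stop("`scores` must be named", call. = FALSE)
  if (any(scores <= 0)) stop("scores must be positive", call. = FALSE)
  quant <- function(r) if (is.null(q)) r else quantize_to_saaty(r, q)
  best <- which.max(scores)
  worst <- which.min(scores)
  if (sum(scores == scores[best]) > 1L || sum(scores == scores[worst]) > 1L)
    warning("ties for best/worst broken by label order")
  a_b <- vapply(scores, function(s) quant(scores[[best]] / s), numeric(1))
  a_w <- vapply(scores, function(s) quant(s / scores[[worst]]), numeric(1))
  a_b[best] <- 1; a_w[worst] <- 1
  ord <- order(-scores, labels)
  pr <- vapply(seq_len(length(scores) - 1L), function(k) {
    quant(scores[[ord[k]]] / scores[[ord[k + 1L]]])
  }, numeric(1))
  list(bwm = bwm_input(labels, best, worst, a_b, a_w),
       fucom = fucom_input(labels[ord], pr))
}

# Minimize a nonsmooth objective over the open weight simplex by multi-start
# Nelder-Mead on log-weights. `starts` is a list of positive start vectors;
# deterministic jittered starts are added from a fixed seed list without
# disturbing the caller's RNG stream.
minimax_simplex <- function(objective, n, starts, n_random = 8L,
                            maxit = 2000L) {
  obj_z <- function(z) {
    w <- exp(z - max(z))
    objective(w / sum(w))
  }
  if (n_random > 0L) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(20231005L)
    for (k in seq_len(n_random))
      starts[[length(starts) + 1L]] <- exp(stats::rnorm(n, sd = 0.5))
  }
  best <- NULL
  for (s in starts) {
    z0 <- log(s / sum(s))
    val0 <- obj_z(z0)
    fit <- stats::optim(z0, obj_z, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    # a second pass from the first optimum tightens nonsmooth corners
    fit2 <- stats::optim(fit$par, obj_z, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-14))
    cand <- if (fit2$value <= fit$value) fit2 else fit
    if (val0 < cand$value) cand <- list(par = z0, value = val0)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  w <- exp(best$par - max(best$par))
  list(weights = w / sum(w), value = best$value)
}

#' Best-worst method weights
#'
#' Solves the original nonlinear BWM program: minimize `xi` subject to
#' `|w_B/w_j - a_Bj| <= xi`, `|w_j/w_W - a_jW| <= xi`, weights positive and
#' summing to 1. Solved as a min-max problem by multi-start local
#' optimization over the log-weight simplex; `xi* = 0` exactly when the
#' comparison vectors are perfectly consistent.
#'
#' @param input A [bwm_input()].
#' @return List with `weights` (named, sums to 1), `xi` (optimal deviation),
#'   and `consistent` (`xi` numerically zero).
#' @export
bwm_weights <- function(input) {
  stopifnot(inherits(input, "bwm_input"))
  n <- length(input$labels)
  b <- input$best; wo <- input$worst
  a_b <- input$best_to_others; a_w <- input$others_to_worst
  objective <- function(w) {
    max(abs(w[b] / w - a_b), abs(w / w[wo] - a_w))
  }
  # consistent-candidate starts: invert each comparison vector
  starts <- list(rep(1, n), 1 / a_b, a_w, (1 / a_b + a_w) / 2)
  sol <- minimax_simplex(objective, n, starts)
  if (!is.finite(sol$value))
    stop("BWM solver failed: non-finite residual", call. = FALSE)
  list(weights = stats::setNames(sol$weights, input$labels),
       xi = sol$value, consistent = sol$value < 1e-8)
}

#' Full consistency method weights
#'
#' Solves the FUCOM program: minimize `chi` subject to
#' `|w_k/w_{k+1} - phi_k| <= chi` and
#' `|w_k/w_{k+2} - phi_k * phi_{k+1}| <= chi` over the weight simplex.
#' For transitively consistent priorities the chained-ratio solution is
#' exact and `chi = 0`.
#'
#' @param input A [fucom_input()].
#' @return List with `weights` (named, in the original ranked order, sums to
#'   1), `chi` (deviation from full consistency), and `consistent`.
#' @export
fucom_weights <- function(input) {
  stopifnot(inherits(input, "fucom_input"))
  n <- length(input$labels)
  phi <- input$priorities
  objective <- function(w) {
    dev <- abs(w[-n] / w[-1] - phi)
    if (n > 2) {
      k <- seq_len(n - 2)
      dev <- c(dev, abs(w[k] / w[k + 2] - phi[k] * phi[k + 1]))
    }
    max(dev)
  }
  chain <- rev(cumprod(c(1, rev(phi))))  # w_k proportional to prod(phi[k..])
  starts <- list(rep(1, n), chain)
  sol <- minimax_simplex(objective, n, starts)
  if (!is.finite(sol$value))
    stop("FUCOM solver failed: non-finite residual", call. = FALSE)
  list(weights = stats::setNames(sol$weights, input$labels),
       chi = sol$value, consistent = sol$value < 1e-8)
}
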