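# Hierarchy synthesis and tie-aware ranking.

#' Synthesize global weights over the leaves of a two-level hierarchy
#'
#' Multiplies each leaf's local weight by the weight of its parent
#' criterion. When both the criteria weights and every local set sum to 1,
#' the global weights sum to 1 (mass conservation).
#'
#' @param criteria_weights Named weight vector over criteria, summing to 1.
#' @param local_weights Named list, one entry per criterion, each a named
#'   weight vector over that criterion's leaves summing to 1.
#' @param tol Tolerance on the unit-sum checks.
#' @return Named numeric vector of global leaf weights, in criteria order.
#' @export
synthesize <- function(criteria_weights, local_weights, tol = 1e-6) {
  if (is.null(names(criteria_weights)))
    stop("`criteria_weights` must be named", call. = FALSE)
  missing <- setdiff(names(criteria_weights), names(local_weights))
  if (length(missing))
    stop("incomplete hierarchy: no local weights for criterion ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (abs(sum(criteria_weights) - 1) > tol)
    stop("criteria weights do not sum to 1", call. = FALSE)
  out <- numeric(0)
  for (crit in names(criteria_weights)) {
    lw <- local_weights[[crit]]
    if (is.null(lw) || is.null(names(lw)) || any(lw <= 0))
      stop(sprintf("criterion '%s' has no valid local weights", crit),
           call. = FALSE)
    if (abs(sum(lw) - 1) > tol)
      stop(sprintf("local weights of '%s' do not sum to 1", crit),
           call. = FALSE)
    out <- c(out, lw * criteria_weights[[crit]])
  }
  out
}

#' Competition ranking of global weights
#'
#' Sorts leaves by weight (descending) after rounding to `tie_decimals`
#' decimals; leaves equal at that precision share the smallest applicable
#' rank and are flagged as tied, and the following rank is skipped
#' (1224-style competition ranking).
#'
#' @param weights Named global weight vector (should sum to 1).
#' @param tie_decimals Rounding precision used for tie detection.
#' @return Data frame of class `smcrisk_ranking` with columns `label`,
#'   `weight`, `percent` (integer percent), `rank`, `tied`, sorted by rank.
#' @export
rank_factors <- function(weights, tie_decimals = 3L) {
  if (is.null(names(weights)))
    stop("`weights` must be named", call. = FALSE)
  rounded <- round(weights, tie_decimals)
  ord <- order(-rounded, names(weights))
  rw <- rounded[ord]
  # competition rank over the rounded values
  rk <- match(rw, rw)  # first position of each value = shared smallest rank
  tied <- duplicated(rw) | duplicated(rw, fromLast = TRUE)
  out <- data.frame(
    label = names(weights)[ord],
    weight = unname(weights[ord]),
    percent = round(100 * unname(weights[ord])),
    rank = rk,
    tied = tied,
    stringsAsFactors = FALSE
  )
  class(out) <- c("smcrisk_ranking", "data.frame")
  out
}

#' @export
print.smcrisk_ranking <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$rank <- paste0(df$rank, ifelse(df$tied, "*", ""))
  df$weight <- sprintf("%.3f", df$weight)
  df$percent <- sprintf("%d %%", df$percent)
  print(df[, c("label", "weight", "percent", "rank")], row.names = FALSE)
  if (any(x$tied)) cat("(* same ranking level)\n")
  invisible(x)
}
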