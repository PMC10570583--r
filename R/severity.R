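# Severity cost model: integer cost factors and normalized severity factors
# from per-class average costs and annual incident counts.

#' Integer severity cost factor
#'
#' Expresses how much costlier an incident of a given severity class is than
#' an incident of the reference class (typically property-damage-only). The
#' ratio of average costs is rounded half-up to the nearest integer, with a
#' floor of 1 so the reference class itself always maps to factor 1.
#'
#' @param avg_cost Average cost per event of the severity class (currency
#'   units). May be a vector.
#' @param reference_cost Average cost per event of the reference class.
#' @return Integer vector of cost factors, each at least 1.
#' @examples
#' cost_factor(1565000, 4711) # 332
#' cost_factor(20235, 4711)   # 4
#' @export
cost_factor <- function(avg_cost, reference_cost) {
  if (any(!is.finite(avg_cost)) || any(avg_cost <= 0))
    stop("`avg_cost` must be positive and finite", call. = FALSE)
  if (length(reference_cost) != 1L || !is.finite(reference_cost) ||
      reference_cost <= 0)
    stop("`reference_cost` must be a single positive number", call. = FALSE)
  # round half up (not banker's rounding)
  f <- floor(avg_cost / reference_cost + 0.5)
  as.integer(pmax(f, 1))
}

#' Rescale an aggregate cost to a different event count
#'
#' Linear rescaling of a total cost reported for `base_count` events to the
#' cost expected for `target_count` events. No rounding is applied.
#'
#' @param total_cost Aggregate cost for `base_count` events.
#' @param base_count Event count the cost was reported for.
#' @param target_count Event count to rescale to.
#' @return Rescaled total cost.
#' @export
scale_total_cost <- function(total_cost, base_count, target_count) {
  if (base_count <= 0) stop("`base_count` must be positive", call. = FALSE)
  if (target_count <= 0) stop("`target_count` must be positive", call. = FALSE)
  total_cost * target_count / base_count
}

#' Average cost per event
#'
#' @param total_cost Aggregate cost.
#' @param n_events Number of events; must be positive.
#' @return `total_cost / n_events`, unrounded.
#' @export
per_event_cost <- function(total_cost, n_events) {
  if (n_events <= 0) stop("`n_events` must be positive", call. = FALSE)
  total_cost / n_events
}

#' Severity schema
#'
#' Bundles an ordered set of severity classes with their per-event costs and
#' annual event counts, derives integer cost factors relative to a reference
#' class, and (after [normalize_severity()]) holds the normalized severity
#' factors: each class's share of the total cost-weighted event count.
#'
#' @param class Character vector of class names (e.g. Fatal, Major, Minor).
#' @param consequence Character vector of consequence labels (same length).
#' @param avg_cost Positive per-event costs.
#' @param count Nonnegative event counts per year.
#' @param reference Name of the reference class (cost factor 1). Defaults to
#'   the class with the lowest average cost.
#' @return An object of class `severity_schema`.
#' @seealso [normalize_severity()], [read_severity_csv()]
#' @export
severity_schema <- function(class, consequence = class, avg_cost, count,
                            reference = NULL) {
  n <- length(class)
  stopifnot(length(consequence) == n, length(avg_cost) == n,
            length(count) == n)
  if (anyDuplicated(class))
    stop("severity class names must be unique", call. = FALSE)
  if (any(!is.finite(avg_cost)) || any(avg_cost <= 0))
    stop("per-event costs must be positive", call. = FALSE)
  if (any(!is.finite(count)) || any(count < 0))
    stop("event counts must be nonnegative", call. = FALSE)
  if (is.null(reference)) reference <- class[which.min(avg_cost)]
  if (!reference %in% class)
    stop(sprintf("reference class '%s' not among classes", reference),
         call. = FALSE)
  cf <- cost_factor(avg_cost, avg_cost[match(reference, class)])
  obj <- structure(
    list(
      classes = data.frame(class = class, consequence = consequence,
                           avg_cost = avg_cost, count = count,
                           stringsAsFactors = FALSE),
      reference_class = reference,
      cost_factors = stats::setNames(cf, class),
      weighted_counts = stats::setNames(as.numeric(cf) * count, class),
      normalized_factors = NULL
    ),
    class = "severity_schema"
  )
  obj
}

#' Normalize cost-weighted counts into severity factors
#'
#' Fills `normalized_factors`: for each class `c`,
#' `cost_factor[c] * count[c] / sum_k(cost_factor[k] * count[k])`. The
#' factors sum to 1 and express the share of total incident cost attributable
#' to the class.
#'
#' @param schema A [severity_schema()].
#' @return The schema with `normalized_factors` filled.
#' @export
normalize_severity <- function(schema) {
  stopifnot(inherits(schema, "severity_schema"))
  wc <- schema$weighted_counts
  total <- sum(wc)
  if (total <= 0)
    stop("degenerate schema: all cost-weighted counts are zero",
         call. = FALSE)
  schema$normalized_factors <- wc / total
  schema
}

#' @export
print.severity_schema <- function(x, ...) {
  cat("Severity schema (reference:", x$reference_class, ")\n")
  df <- x$classes
  df$cost_factor <- x$cost_factors[df$class]
  df$weighted <- x$weighted_counts[df$class]
  if (!is.null(x$normalized_factors))
    df$normalized <- round(x$normalized_factors[df$class], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# strip thousands separators: ASCII comma/apostrophe and the Unicode prime
# characters some published tables use
strip_separators <- function(x) {
  gsub("[,'′ʹ’]", "", trimws(as.character(x)))
}

#' Read a severity schema from CSV
#'
#' Expected columns: `class,consequence,avg_cost,count`. Numeric fields may
#' contain thousands separators (commas inside quotes, apostrophes, or prime
#' characters); they are stripped on read.
#'
#' @param path CSV file path.
#' @param reference Reference class passed to [severity_schema()].
#' @return A normalized [severity_schema()].
#' @export
read_severity_csv <- function(path, reference = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("class", "consequence", "avg_cost", "count")
  if (!all(need %in% names(df)))
    stop("severity CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  schema <- severity_schema(
    class = df$class,
    consequence = df$consequence,
    avg_cost = as.numeric(strip_separators(df$avg_cost)),
    count = as.numeric(strip_separators(df$count)),
    reference = reference
  )
  normalize_severity(schema)
}

#' Serialize a severity schema to JSON
#'
#' @param schema A [severity_schema()].
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_severity_json <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "severity_schema"))
  out <- list(
    reference_class = schema$reference_class,
    cost_factors = as.list(schema$cost_factors),
    normalized_factors = as.list(schema$normalized_factors)
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
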