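# Evidence tables: per-factor, per-severity-class shares, severity-weighted
# and aggregated into per-factor importance scores.

#' Severity-weighted share
#'
#' Multiplies a raw share (fraction of incidents of a severity class
#' attributable to a factor) by the class's normalized severity factor and
#' expresses the result in percent.
#'
#' @param raw_share Fraction in \[0, 1\].
#' @param severity_factor Normalized severity factor in \[0, 1\].
#' @return Weighted share in percent.
#' @export
weighted_share <- function(raw_share, severity_factor) {
  if (any(!is.finite(raw_share)) || any(raw_share < 0) || any(raw_share > 1))
    stop("`raw_share` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(severity_factor)) || any(severity_factor < 0) ||
      any(severity_factor > 1))
    stop("`severity_factor` must lie in [0, 1]", call. = FALSE)
  raw_share * severity_factor * 100
}

#' Evidence table for one criterion group
#'
#' Holds severity-weighted shares (percent) for each (factor, severity class)
#' cell of a criterion group. Shares may be supplied already weighted, or raw
#' (fractions of each class) together with a normalized [severity_schema()]
#' used to weight them.
#'
#' @param group Criterion group label.
#' @param shares Numeric matrix, severity classes in rows, factors in
#'   columns, with dimnames. Percent when `weighted = TRUE`; raw fractions
#'   in \[0, 1\] otherwise.
#' @param weighted Logical; are the shares already severity-weighted?
#' @param schema A normalized [severity_schema()]; required when
#'   `weighted = FALSE`. Row names of `shares` must match its classes.
#' @return An object of class `evidence_table`.
#' @export
evidence_table <- function(group, shares, weighted = TRUE, schema = NULL) {
  stopifnot(is.matrix(shares), !is.null(rownames(shares)),
            !is.null(colnames(shares)))
  if (any(!is.finite(shares)) || any(shares < 0))
    stop("shares must be nonnegative and finite", call. = FALSE)
  if (!weighted) {
    if (is.null(schema) || is.null(schema$normalized_factors))
      stop("raw shares require a normalized severity schema", call. = FALSE)
    sf <- schema$normalized_factors[rownames(shares)]
    if (anyNA(sf))
      stop("shares rows must match the schema's severity classes",
           call. = FALSE)
    shares <- sweep(shares, 1, sf, function(raw, f) weighted_share(raw, f))
  }
  structure(
    list(group = group,
         factors = colnames(shares),
         classes = rownames(shares),
         weighted_share = shares),
    class = "evidence_table"
  )
}

#' Per-factor importance scores
#'
#' Sums severity-weighted shares over the severity classes for each factor of
#' an evidence table. Scores are kept at full precision internally; the
#' published convention is to display them at 1 decimal.
#'
#' @param table An [evidence_table()].
#' @return Named numeric vector of scores in percent, one per factor.
#' @export
importance_scores <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  m <- table$weighted_share
  if (anyNA(m))
    stop("incomplete evidence table: missing weighted share cells",
         call. = FALSE)
  colSums(m)
}

#' Ratio of two importance scores
#'
#' The raw ratio later quantized onto the Saaty scale when building a
#' pairwise comparison matrix.
#'
#' @param score_i,score_j Importance scores in percent; `score_j` must be
#'   positive. Optionally named, for error messages.
#' @return `score_i / score_j`.
#' @export
score_ratio <- function(score_i, score_j) {
  if (score_j <= 0) {
    lab_i <- if (!is.null(names(score_i))) names(score_i)[1] else "i"
    lab_j <- if (!is.null(names(score_j))) names(score_j)[1] else "j"
    stop(sprintf("cannot form score ratio %s/%s: denominator is not positive",
                 lab_i, lab_j), call. = FALSE)
  }
  unname(score_i / score_j)
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("Evidence table:", x$group, "\n")
  m <- rbind(x$weighted_share, Sum = colSums(x$weighted_share))
  print(round(m, 1))
  invisible(x)
}

#' Read evidence tables from CSV
#'
#' Expected columns: `group,factor,class,share_percent` (or `share` for raw
#' fractions). A leading comment line `# weighted: true|false` states whether
#' the shares are already severity-weighted; it defaults to `true`. Factors
#' and classes keep their order of first appearance.
#'
#' @param path CSV file path.
#' @param schema Normalized [severity_schema()], required when the file
#'   declares `weighted: false`.
#' @return Named list of [evidence_table()] objects, one per group.
#' @export
read_evidence_csv <- function(path, schema = NULL) {
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  weighted <- TRUE
  flag <- grep("weighted", meta, value = TRUE)
  if (length(flag))
    weighted <- grepl("true", tolower(flag[1]))
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE)
  value_col <- if ("share_percent" %in% names(df)) "share_percent" else "share"
  need <- c("group", "factor", "class", value_col)
  if (!all(need %in% names(df)))
    stop("evidence CSV must have columns: group, factor, class, ",
         "share_percent (or share)", call. = FALSE)
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    facs <- unique(sub$factor)
    cls <- unique(sub$class)
    m <- matrix(NA_real_, nrow = length(cls), ncol = length(facs),
                dimnames = list(cls, facs))
    m[cbind(match(sub$class, cls), match(sub$factor, facs))] <-
      as.numeric(sub[[value_col]])
    if (anyNA(m))
      stop(sprintf("evidence group '%s' has missing (factor, class) cells", g),
           call. = FALSE)
    # files store percent even for raw shares, matching the published tables
    if (!weighted) m <- m / 100
    out[[g]] <- evidence_table(g, m, weighted = weighted, schema = schema)
  }
  out
}
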