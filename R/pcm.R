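# Pairwise comparison matrices: construction from importance scores via
# Saaty-scale quantization, validation, and cardinal consistency checking.

#' Construct a pairwise comparison matrix
#'
#' A PCM is a positive reciprocal square matrix: `a_ij > 0`,
#' `a_ji = 1/a_ij`, unit diagonal. Entry `a_ij` encodes how much more
#' important factor `i` is than factor `j`. Matrices above the Saaty scale
#' limit of nine factors are rejected unless `allow_large = TRUE`.
#'
#' @param entries Numeric square matrix.
#' @param labels Factor labels; defaults to the matrix dimnames.
#' @param allow_large Permit more than nine factors.
#' @return An object of class `pcm` (a labelled matrix).
#' @export
pcm <- function(entries, labels = NULL, allow_large = FALSE) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (n != ncol(entries)) stop("PCM must be square", call. = FALSE)
  if (n < 2) stop("PCM needs at least two factors", call. = FALSE)
  if (n > 9 && !allow_large)
    stop("PCM has more than 9 factors (Saaty scale limit); ",
         "use allow_large = TRUE to override", call. = FALSE)
  if (is.null(labels)) labels <- rownames(entries)
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  stopifnot(length(labels) == n)
  dimnames(entries) <- list(labels, labels)
  x <- structure(entries, class = c("pcm", "matrix"))
  issues <- validate_pcm(x)
  if (nrow(issues))
    stop("invalid PCM: ", paste(issues$message, collapse = "; "),
         call. = FALSE)
  x
}

#' Validate pairwise comparison matrix invariants
#'
#' Report-based check: every violated invariant (non-positive entry, broken
#' reciprocity beyond tolerance, non-unit diagonal) is listed with its
#' indices. An empty report means the matrix is a valid PCM.
#'
#' @param x Matrix or `pcm`.
#' @param tol Absolute tolerance for reciprocity and the unit diagonal.
#' @return Data frame with columns `type`, `i`, `j`, `message`.
#' @export
validate_pcm <- function(x, tol = 1e-9) {
  m <- unclass(as.matrix(x))
  n <- nrow(m)
  issues <- list()
  add <- function(type, i, j, msg)
    issues[[length(issues) + 1L]] <<-
      data.frame(type = type, i = i, j = j, message = msg,
                 stringsAsFactors = FALSE)
  if (n != ncol(m)) {
    add("shape", NA, NA, "matrix is not square")
    return(do.call(rbind, issues))
  }
  for (i in seq_len(n)) {
    if (!is.finite(m[i, i]) || abs(m[i, i] - 1) > tol)
      add("diagonal", i, i, sprintf("a[%d,%d] = %g is not 1", i, i, m[i, i]))
    for (j in seq_len(n)) {
      if (!is.finite(m[i, j]) || m[i, j] <= 0)
        add("positivity", i, j,
            sprintf("a[%d,%d] = %g is not positive", i, j, m[i, j]))
    }
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (m[i, j] > 0 && m[j, i] > 0 &&
        abs(m[j, i] - 1 / m[i, j]) > tol * max(1, 1 / m[i, j]))
      add("reciprocity", j, i,
          sprintf("a[%d,%d] = %g is not 1/a[%d,%d]", j, i, m[j, i], i, j))
  }
  if (!length(issues))
    return(data.frame(type = character(), i = integer(), j = integer(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Cardinal (transitive) consistency check
#'
#' A PCM is cardinally consistent when `a_ik = a_ij * a_jk` for every triple
#' `(i, j, k)`. Judgment matrices quantized onto the Saaty scale usually
#' violate this; the consistency ratio ([pcm_consistency()]) quantifies how
#' badly.
#'
#' @param x A valid `pcm`.
#' @param tol Relative tolerance on `a_ik / (a_ij * a_jk) - 1`.
#' @return List with `consistent` (logical), `max_violation` (worst relative
#'   deviation), and `worst_triple` (indices `i, j, k` attaining it).
#' @export
is_cardinally_consistent <- function(x, tol = 1e-9) {
  m <- unclass(as.matrix(x))
  n <- nrow(m)
  worst <- c(i = 1L, j = 1L, k = 1L)
  worst_dev <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    dev <- abs(m[i, k] / (m[i, j] * m[j, k]) - 1)
    if (dev > worst_dev) {
      worst_dev <- dev
      worst <- c(i = i, j = j, k = k)
    }
  }
  list(consistent = worst_dev <= tol, max_violation = worst_dev,
       worst_triple = worst)
}

#' Saaty-scale quantizer
#'
#' Settings for mapping raw importance-score ratios onto the discrete Saaty
#' scale `{1/9, ..., 1/2, 1, 2, ..., 9}`. A ratio `r >= 1` maps to
#' `floor(r)`, bumped up by one when its fractional part reaches
#' `ceil_threshold`, clamped to `[1, scale_max]`; ratios below 1 map to the
#' reciprocal of the quantized inverse, so reciprocity holds by construction.
#' Explicit overrides let an expert pin individual matrix cells.
#'
#' @param scale_max Upper end of the scale (9, the Saaty limit).
#' @param ceil_threshold Fractional part at which to round up; default 0.25.
#' @param overrides Named numeric vector of pinned intensities; names are
#'   `"i|j"` pairs of factor labels, values positive Saaty intensities.
#' @return An object of class `saaty_quantizer`.
#' @export
saaty_quantizer <- function(scale_max = 9L, ceil_threshold = 0.25,
                            overrides = NULL) {
  if (!identical(as.integer(scale_max), 9L))
    stop("`scale_max` must be 9 (the Saaty scale)", call. = FALSE)
  if (ceil_threshold < 0 || ceil_threshold >= 1)
    stop("`ceil_threshold` must lie in [0, 1)", call. = FALSE)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be named 'i|j'", call. = FALSE)
    if (any(overrides <= 0))
      stop("invalid override: intensities must be positive", call. = FALSE)
  }
  structure(list(scale_max = as.integer(scale_max),
                 ceil_threshold = ceil_threshold,
                 overrides = overrides),
            class = "saaty_quantizer")
}

#' Quantize a ratio onto the Saaty scale
#'
#' @param ratio Positive score ratio(s).
#' @param q A [saaty_quantizer()].
#' @return Intensity in `{1/9, ..., 1, ..., 9}`; vectorized over `ratio`.
#'   Satisfies `quantize(1/r) == 1/quantize(r)`.
#' @export
quantize_to_saaty <- function(ratio, q = saaty_quantizer()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("`ratio` must be positive and finite", call. = FALSE)
  one <- function(r) {
    if (r < 1) return(1 / one(1 / r))
    f <- floor(r)
    v <- f + as.numeric(r - f >= q$ceil_threshold)
    min(max(v, 1), q$scale_max)
  }
  vapply(ratio, one, numeric(1))
}

#' Build a PCM from importance scores
#'
#' Upper-triangle entries are quantized score ratios
#' `quantize(score_i / score_j)`; lower-triangle entries are their
#' reciprocals and the diagonal is 1. Expert overrides in the quantizer are
#' applied last (an override on `(i, j)` forces `a_ji` to its reciprocal).
#' With `q = NULL` the raw ratios are used unquantized, which yields a
#' perfectly consistent matrix.
#'
#' @param scores Named vector of positive importance scores (percent).
#' @param q A [saaty_quantizer()], or `NULL` to skip quantization.
#' @return A `pcm`.
#' @export
build_from_scores <- function(scores, q = saaty_quantizer()) {
  labels <- names(scores)
  if (is.null(labels)) stop("`scores` must be named", call. = FALSE)
  n <- length(scores)
  if (n < 2) stop("need at least two factors", call. = FALSE)
  if (any(scores <= 0)) {
    bad <- labels[scores <= 0][1]
    stop(sprintf("cannot build PCM: score of '%s' is not positive", bad),
         call. = FALSE)
  }
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- score_ratio(scores[i], scores[j])
    a <- if (is.null(q)) r else quantize_to_saaty(r, q)
    m[i, j] <- a
    m[j, i] <- 1 / a
  }
  if (!is.null(q) && !is.null(q$overrides)) {
    for (nm in names(q$overrides)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
      idx <- match(pair, labels)
      if (anyNA(idx) || length(idx) != 2L)
        stop(sprintf("override '%s' does not name two known factors", nm),
             call. = FALSE)
      v <- q$overrides[[nm]]
      m[idx[1], idx[2]] <- v
      m[idx[2], idx[1]] <- 1 / v
    }
  }
  pcm(m, labels)
}
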