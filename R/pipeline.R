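# Study configuration, file formats, the end-to-end pipeline
# (severity -> evidence -> PCM -> weights -> consistency -> synthesis ->
# ranking), and report rendering.

# "1/3"-style rationals or plain decimals
parse_rational <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("^[0-9.eE+-]+/[0-9.eE+-]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      as.numeric(parts[1]) / as.numeric(parts[2])
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a pairwise comparison matrix from JSON
#'
#' Format: `{"labels": [...], "entries": [[...]]}`. Entries may be decimals
#' or exact rationals written as strings (`"1/3"`).
#'
#' @param path JSON file path.
#' @return A `pcm`.
#' @export
read_pcm_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  entries <- do.call(rbind, lapply(obj$entries, parse_rational))
  pcm(entries, labels = unlist(obj$labels))
}

#' Write a pairwise comparison matrix to JSON
#'
#' Entries are emitted as decimals at full precision.
#'
#' @param x A `pcm`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @export
write_pcm_json <- function(x, path = NULL) {
  m <- unclass(as.matrix(x))
  out <- list(labels = rownames(m),
              entries = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  json <- jsonlite::toJSON(out, digits = I(17), auto_unbox = FALSE,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# inline matrix block from a hierarchy config: list(labels, entries)
parse_inline_pcm <- function(block) {
  entries <- block$entries
  if (is.list(entries)) entries <- do.call(rbind, lapply(entries, parse_rational))
  pcm(as.matrix(entries), labels = unlist(block$labels))
}

#' Read a hierarchy configuration (YAML or JSON)
#'
#' The config names the goal, the criteria (each with an `id`, a `label`,
#' its leaf `factors` as an id-to-label map, and either an `evidence_group`
#' naming the evidence block that drives its sub-criteria matrix or an
#' inline `pcm`), and the criteria-level comparison matrix `criteria_pcm`
#' (expert-supplied, as the criteria level is judged semi-qualitatively).
#' Matrix entries accept `"1/3"`-style rationals.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with `goal`, `criteria`, and `criteria_pcm` (a `pcm` or
#'   `NULL`).
#' @export
read_hierarchy_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  }
  if (is.null(cfg$goal) || is.null(cfg$criteria))
    stop("hierarchy config needs `goal` and `criteria`", call. = FALSE)
  criteria <- lapply(cfg$criteria, function(cr) {
    if (is.null(cr$id)) stop("each criterion needs an `id`", call. = FALSE)
    if (!is.null(cr$pcm)) cr$pcm <- parse_inline_pcm(cr$pcm)
    if (is.null(cr$label)) cr$label <- cr$id
    cr
  })
  cpcm <- if (!is.null(cfg$criteria_pcm)) parse_inline_pcm(cfg$criteria_pcm)
  ids <- vapply(criteria, `[[`, character(1), "id")
  if (!is.null(cpcm) && !identical(rownames(cpcm), ids))
    stop("criteria_pcm labels must match the criteria ids in order",
         call. = FALSE)
  leaves <- unlist(lapply(criteria, function(cr) names(cr$factors)))
  if (anyDuplicated(leaves))
    stop("each leaf factor may appear under exactly one criterion",
         call. = FALSE)
  list(goal = cfg$goal, criteria = criteria, criteria_pcm = cpcm)
}

#' Study configuration
#'
#' Collects the inputs and settings of one ranking study. File paths are
#' read lazily by [run_pipeline()]; already-constructed objects (a
#' [severity_schema()], a list of [evidence_table()], a parsed hierarchy)
#' are accepted as-is.
#'
#' @param severity Path to a severity CSV, or a normalized
#'   [severity_schema()].
#' @param evidence Path to an evidence CSV, or a named list of
#'   [evidence_table()].
#' @param hierarchy Path to a hierarchy config, or the parsed list.
#' @param ceil_threshold Saaty quantizer rounding threshold.
#' @param overrides Expert overrides, passed to [saaty_quantizer()].
#' @param method Weighting method, `"eigen"` or `"rowmean"`.
#' @param strict_cr Abort (rather than warn) when any matrix has
#'   `CR >= 0.10`.
#' @param tie_decimals Rounding precision for tie detection in the ranking.
#' @return An object of class `study_config`.
#' @export
study_config <- function(severity, evidence, hierarchy,
                         ceil_threshold = 0.25, overrides = NULL,
                         method = c("eigen", "rowmean"),
                         strict_cr = FALSE, tie_decimals = 3L) {
  structure(list(severity = severity, evidence = evidence,
                 hierarchy = hierarchy,
                 quantizer = saaty_quantizer(ceil_threshold = ceil_threshold,
                                             overrides = overrides),
                 method = match.arg(method),
                 strict_cr = isTRUE(strict_cr),
                 tie_decimals = as.integer(tie_decimals)),
            class = "study_config")
}

# resolve config inputs into in-memory objects
load_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  schema <- config$severity
  if (is.character(schema)) schema <- read_severity_csv(schema)
  if (!inherits(schema, "severity_schema"))
    stop("severity input is neither a path nor a severity_schema",
         call. = FALSE)
  if (is.null(schema$normalized_factors)) schema <- normalize_severity(schema)
  evidence <- config$evidence
  if (is.character(evidence))
    evidence <- read_evidence_csv(evidence, schema = schema)
  hierarchy <- config$hierarchy
  if (is.character(hierarchy)) hierarchy <- read_hierarchy_config(hierarchy)
  list(schema = schema, evidence = evidence, hierarchy = hierarchy)
}

# per-criterion PCMs: evidence-driven groups are quantized from importance
# scores; otherwise the criterion carries an inline expert matrix or (for
# degenerate groups, e.g. a single leaf) direct local weights
build_level_pcms <- function(study, quantizer) {
  scores <- lapply(study$evidence, importance_scores)
  pcms <- list()
  direct <- list()
  for (cr in study$hierarchy$criteria) {
    if (!is.null(cr$pcm)) {
      pcms[[cr$id]] <- cr$pcm
    } else if (!is.null(cr$weights)) {
      w <- unlist(cr$weights)
      if (any(w <= 0))
        stop(sprintf("criterion '%s': direct weights must be positive",
                     cr$id), call. = FALSE)
      direct[[cr$id]] <- w / sum(w)
    } else if (!is.null(cr$evidence_group)) {
      sc <- scores[[cr$evidence_group]]
      if (is.null(sc))
        stop(sprintf("criterion '%s': no evidence group '%s'", cr$id,
                     cr$evidence_group), call. = FALSE)
      if (length(sc) == 1L) {
        direct[[cr$id]] <- stats::setNames(1, names(sc))
      } else {
        pcms[[cr$id]] <- build_from_scores(sc, quantizer)
      }
    } else {
      stop(sprintf(
        "criterion '%s' has no PCM, weights, or evidence group", cr$id),
        call. = FALSE)
    }
  }
  list(scores = scores, pcms = pcms, direct = direct)
}

#' Run the full severity-weighted ranking pipeline
#'
#' Executes, in order: severity normalization, evidence aggregation into
#' importance scores, pairwise-matrix construction (quantized from scores
#' for evidence-driven criteria, expert-supplied at the criteria level),
#' weighting, consistency evaluation, hierarchy synthesis, and tie-aware
#' ranking. Any matrix with `CR >= 0.10` aborts the run under
#' `strict_cr = TRUE` and warns otherwise.
#'
#' @param config A [study_config()].
#' @return An object of class `smcrisk_report`.
#' @export
run_pipeline <- function(config) {
  study <- load_study(config)
  hier <- study$hierarchy
  ids <- vapply(hier$criteria, `[[`, character(1), "id")
  if (is.null(hier$criteria_pcm) && length(ids) > 1L)
    stop("pipeline stage 'criteria weighting': no criteria_pcm in hierarchy",
         call. = FALSE)
  lv <- build_level_pcms(study, config$quantizer)
  pcms <- lv$pcms
  if (!is.null(hier$criteria_pcm))
    pcms <- c(list(criteria = hier$criteria_pcm), pcms)

  weights <- lapply(pcms, ahp_weights, method = config$method)
  reports <- lapply(pcms, pcm_consistency)
  bad <- names(reports)[!vapply(reports, `[[`, logical(1), "passed")]
  if (length(bad)) {
    msg <- sprintf("consistency failure (CR >= 0.10) in: %s",
                   paste(bad, collapse = ", "))
    if (config$strict_cr) stop(msg, call. = FALSE) else warning(msg)
  }

  crit_w <- if (!is.null(hier$criteria_pcm)) weights$criteria
            else stats::setNames(1, ids)
  local_w <- c(weights[setdiff(names(pcms), "criteria")], lv$direct)
  local_w <- local_w[intersect(ids, names(local_w))]
  global_w <- synthesize(crit_w, local_w)
  ranking <- rank_factors(global_w, tie_decimals = config$tie_decimals)

  labels <- unlist(lapply(hier$criteria, `[[`, "factors"))
  structure(
    list(goal = hier$goal,
         settings = list(method = config$method,
                         ceil_threshold = config$quantizer$ceil_threshold,
                         strict_cr = config$strict_cr,
                         tie_decimals = config$tie_decimals),
         schema = study$schema,
         scores = lv$scores,
         pcms = pcms,
         normalized = lapply(pcms, column_normalize),
         criteria_weights = crit_w,
         local_weights = local_w,
         consistency = reports,
         global_weights = global_w,
         ranking = ranking,
         factor_labels = labels),
    class = "smcrisk_report"
  )
}

#' @export
print.smcrisk_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Render a pipeline report
#'
#' `"json"` renders a loss-less machine-readable report (full-precision
#' values plus display fields at the conventional precisions: weights 3,
#' lambda-max 4, CR 6 decimals, percents at 1). `"text"` renders the
#' normalized matrices, weight tables, consistency table, and the ranking
#' with ties marked `*`.
#'
#' @param report An `smcrisk_report`.
#' @param format `"json"` or `"text"`.
#' @return A JSON string, or a character vector of text lines.
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "smcrisk_report"))
  format <- match.arg(format)
  if (is.null(report$ranking) || !nrow(report$ranking))
    stop("report has no ranked leaves; nothing to render", call. = FALSE)
  if (format == "json") {
    cons <- lapply(report$consistency, function(cr) list(
      lambda_max = cr$lambda_max, ci = cr$ci, ri = cr$ri, cr = cr$cr,
      n = cr$n, passed = cr$passed,
      display = list(lambda_max = round(cr$lambda_max, 4),
                     cr = round(cr$cr, 6))))
    obj <- list(
      goal = report$goal,
      settings = report$settings,
      severity = list(
        cost_factors = as.list(report$schema$cost_factors),
        normalized_factors = as.list(report$schema$normalized_factors)),
      importance_scores = lapply(report$scores, function(s)
        as.list(round(s, 10))),
      pcms = lapply(report$pcms, function(p) list(
        labels = rownames(p),
        entries = lapply(seq_len(nrow(p)),
                         function(i) unname(unclass(p)[i, ])))),
      criteria_weights = as.list(report$criteria_weights),
      local_weights = lapply(report$local_weights, as.list),
      consistency = cons,
      global_weights = as.list(report$global_weights),
      ranking = report$ranking
    )
    return(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                            dataframe = "columns", pretty = TRUE))
  }
  lines <- c(sprintf("Goal: %s", report$goal),
             sprintf("Method: %s | quantizer threshold: %.2f",
                     report$settings$method,
                     report$settings$ceil_threshold), "")
  lines <- c(lines, "Consistency:")
  for (nm in names(report$consistency)) {
    cr <- report$consistency[[nm]]
    lines <- c(lines, sprintf(
      "  %-16s n=%d lambda_max=%.4f CI=%.4f RI=%.2f CR=%.6f %s",
      nm, cr$n, cr$lambda_max, cr$ci, cr$ri, cr$cr,
      if (cr$passed) "(CR < 0.10)" else "(CR >= 0.10!)"))
  }
  lines <- c(lines, "", "Local weights:")
  for (nm in names(report$local_weights)) {
    w <- report$local_weights[[nm]]
    lines <- c(lines, sprintf("  %-16s %s", nm,
                              paste(sprintf("%s=%.3f", names(w), w),
                                    collapse = " ")))
  }
  cw <- report$criteria_weights
  lines <- c(lines, sprintf("  %-16s %s", "criteria",
                            paste(sprintf("%s=%.3f", names(cw), cw),
                                  collapse = " ")))
  lines <- c(lines, "", "Ranking:")
  rk <- report$ranking
  for (i in seq_len(nrow(rk))) {
    lab <- report$factor_labels[[rk$label[i]]]
    if (is.null(lab)) lab <- rk$label[i]
    lines <- c(lines, sprintf("  %2d%s %-24s %.3f  %d %%",
                              rk$rank[i], ifelse(rk$tied[i], "*", " "),
                              paste0(rk$label[i], " ", lab), rk$weight[i],
                              rk$percent[i]))
  }
  if (any(rk$tied)) lines <- c(lines, "  (* same ranking level)")
  lines
}

#' Compare AHP, BWM, and FUCOM rankings on one study
#'
#' Runs the severity-weighted pipeline, then re-derives the criteria-level
#' and sub-criteria-level weights with the best-worst method and the full
#' consistency method. Sub-criteria comparison vectors come from the same
#' severity-weighted importance scores via [derive_comparator_inputs()];
#' criteria-level vectors are read off the expert criteria matrix (rows of
#' the best criterion, column of the worst, consecutive ratios for FUCOM),
#' ordered by the AHP criteria weights.
#'
#' @param config A [study_config()].
#' @param methods Subset of `c("ahp", "bwm", "fucom")`.
#' @return List with `weights` (methods x leaves matrix), `ranks` (same
#'   shape, competition ranks), `xi` / `chi` diagnostics, and
#'   `max_divergence` (largest absolute weight difference between any two
#'   methods).
#' @export
compare_methods <- function(config, methods = c("ahp", "bwm", "fucom")) {
  methods <- match.arg(methods, several.ok = TRUE)
  report <- run_pipeline(config)
  study <- load_study(config)
  q <- config$quantizer
  crit_pcm <- report$pcms$criteria
  crit_ids <- names(report$criteria_weights)

  globals <- list()
  diagnostics <- list()
  if ("ahp" %in% methods) globals$ahp <- report$global_weights

  solve_level <- function(solver, from_scores, from_pcm) {
    crit_in <- from_pcm(crit_pcm, report$criteria_weights)
    crit_sol <- solver(crit_in)
    locals <- list()
    for (cr in study$hierarchy$criteria) {
      sc <- report$scores[[cr$evidence_group]]
      if (is.null(sc)) {
        # criteria without evidence keep their AHP local weights
        locals[[cr$id]] <- report$local_weights[[cr$id]]
      } else {
        locals[[cr$id]] <- solver(from_scores(sc))$weights
      }
    }
    list(global = synthesize(crit_sol$weights[crit_ids], locals),
         crit = crit_sol)
  }

  if ("bwm" %in% methods) {
    res <- solve_level(
      bwm_weights,
      from_scores = function(sc) derive_comparator_inputs(sc, q)$bwm,
      from_pcm = bwm_from_pcm)
    globals$bwm <- res$global
    diagnostics$bwm_xi <- res$crit$xi
  }
  if ("fucom" %in% methods) {
    res <- solve_level(
      fucom_weights,
      from_scores = function(sc) derive_comparator_inputs(sc, q)$fucom,
      from_pcm = fucom_from_pcm)
    globals$fucom <- res$global
    diagnostics$fucom_chi <- res$crit$chi
  }

  leaves <- names(report$global_weights)
  wmat <- do.call(rbind, lapply(globals, function(g) g[leaves]))
  colnames(wmat) <- leaves
  ranks <- t(apply(wmat, 1, function(w) {
    rk <- rank_factors(stats::setNames(w, leaves))
    rk$rank[match(leaves, rk$label)]
  }))
  colnames(ranks) <- leaves
  div <- if (nrow(wmat) > 1) {
    max(vapply(utils::combn(nrow(wmat), 2, simplify = FALSE),
               function(p) max(abs(wmat[p[1], ] - wmat[p[2], ])),
               numeric(1)))
  } else 0
  c(list(weights = wmat, ranks = ranks, max_divergence = div), diagnostics)
}

# BWM vectors read off an existing PCM: the best criterion's row and the
# worst criterion's column, best/worst taken from reference weights
bwm_from_pcm <- function(x, ref_weights) {
  m <- unclass(as.matrix(x))
  b <- which.max(ref_weights)
  w <- which.min(ref_weights)
  bwm_input(rownames(m), b, w, m[b, ], m[, w])
}

# FUCOM priorities from the consecutive entries of a PCM, criteria ordered
# by decreasing reference weight
fucom_from_pcm <- function(x, ref_weights) {
  m <- unclass(as.matrix(x))
  ord <- order(-ref_weights, rownames(m))
  n <- nrow(m)
  phi <- vapply(seq_len(n - 1),
                function(k) m[ord[k], ord[k + 1]], numeric(1))
  fucom_input(rownames(m)[ord], pmax(phi, 1))
}
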