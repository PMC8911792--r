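#' Optimal extraction conditions and yield report
#'
#' Identifies, per response, the measured condition with maximal and minimal
#' mean yield; computes fold-changes between a pair of conditions (default:
#' 65 vs 30 degC at 60 % v/v ethanol, the temperature contrast at the yield
#' peak); and selects a consensus optimum — the condition that is argmax for
#' the most responses, ties resolved in favour of the candidate with higher
#' TPC (or higher first-response) mean. Optimization is argmax over measured
#' conditions; optionally each response's fitted parametric curve is densely
#' sampled and the sample maximum reported alongside as an exploratory
#' refinement (a curve through a grid interpolates, it is not a fitted
#' response surface, so the refined value can only confirm or marginally
#' exceed the grid optimum).
#'
#' @param ds An [extraction_dataset()].
#' @param refine Also report the dense-sampling maximum of each response's
#'   cubic curve? Default `FALSE`.
#' @param fold_pairs List of `list(num = c(t, C), den = c(t, C))` condition
#'   pairs for the fold-change table; the default contrasts `c(65, 60)` over
#'   `c(30, 60)` when both exist, otherwise the per-dataset extremes of
#'   temperature at the concentration level with the highest mean yield.
#' @param samples_per_interval Dense-sampling resolution for `refine`
#'   (default 1000 points per spline interval).
#' @return An `optimization_report`: list with `optima`, `minima`,
#'   `fold_changes` (tibbles), `consensus` (one-row tibble) and, when
#'   `refine = TRUE`, `refined` (tibble with the sampled-curve maxima).
#' @examples
#' optimize_extraction(load_fixture("table1"))
#' @export
optimize_extraction <- function(ds, refine = FALSE, fold_pairs = NULL,
                                samples_per_interval = 1000) {
  stopifnot(inherits(ds, "extraction_dataset"))
  resp <- extraction_responses(ds)

  per_resp <- function(which) {
    dplyr::bind_rows(lapply(resp, function(r) {
      out <- extreme_condition(ds, r, which)
      out$response <- r
      out[c("response", "temperature_C", "concentration_pct", "mean", "sd")]
    }))
  }
  optima <- per_resp("max")
  minima <- per_resp("min")

  # consensus: the condition that is argmax for the most responses
  key <- paste(optima$temperature_C, optima$concentration_pct)
  tally <- sort(table(key), decreasing = TRUE)
  top <- names(tally)[tally == max(tally)]
  ds_key <- paste(ds$temperature_C, ds$concentration_pct)
  if (length(top) > 1L) {
    # tie-break: among tied conditions take the higher first-response mean
    lead <- ds[[paste0(resp[[1]], "_mean")]][match(top, ds_key)]
    top <- top[[which.max(lead)]]
  } else {
    top <- top[[1]]
  }
  cons_idx <- match(top, ds_key)
  consensus <- tibble::tibble(
    temperature_C = ds$temperature_C[cons_idx],
    concentration_pct = ds$concentration_pct[cons_idx],
    n_responses_maximal = as.integer(max(tally))
  )

  if (is.null(fold_pairs)) {
    has_default <- !inherits(try(condition_row(ds, c(65, 60)), silent = TRUE),
                             "try-error") &&
      !inherits(try(condition_row(ds, c(30, 60)), silent = TRUE), "try-error")
    fold_pairs <- if (has_default) {
      list(list(num = c(65, 60), den = c(30, 60)))
    } else {
      t_rng <- range(attr(ds, "temperature_levels"))
      c_star <- consensus$concentration_pct
      list(list(num = c(t_rng[[2]], c_star), den = c(t_rng[[1]], c_star)))
    }
  }
  fold_changes <- dplyr::bind_rows(lapply(fold_pairs, function(p) {
    tibble::tibble(
      response = resp,
      num_temperature_C = p$num[[1]], num_concentration_pct = p$num[[2]],
      den_temperature_C = p$den[[1]], den_concentration_pct = p$den[[2]],
      fold_change = unname(vapply(resp, function(r) {
        fold_change(ds, r, p$num, p$den)
      }, numeric(1)))
    )
  }))

  rep <- list(
    responses = resp,
    units = extraction_units(ds),
    optima = optima,
    minima = minima,
    consensus = consensus,
    fold_changes = fold_changes
  )
  if (isTRUE(refine)) {
    rep$refined <- dplyr::bind_rows(lapply(resp, function(r) {
      crv <- fit_parametric_spline(order_points(ds, r))
      samp <- sample_curve(crv, per_interval = samples_per_interval)
      i <- which.max(samp$response)
      tibble::tibble(
        response = r,
        s = samp$s[[i]],
        temperature_C = samp$t[[i]],
        concentration_pct = samp$C[[i]],
        value = samp$response[[i]]
      )
    }))
  }
  structure(rep, class = "optimization_report")
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("<optimization_report>\n")
  cat(sprintf("consensus optimum: %g degC, %g%% v/v (maximal for %d response(s))\n",
              x$consensus$temperature_C, x$consensus$concentration_pct,
              x$consensus$n_responses_maximal))
  cat("per-response optima:\n")
  print(x$optima)
  cat("fold-changes:\n")
  print(x$fold_changes)
  if (!is.null(x$refined)) {
    cat("curve-refined maxima (exploratory):\n")
    print(x$refined)
  }
  invisible(x)
}

#' Serialize an optimization report
#'
#' Deterministic rendering of an [optimize_extraction()] report, either as
#' JSON or as a Markdown document whose yield table mirrors the factorial
#' layout with the optimum cell of each response flagged with `*`.
#'
#' @param rep An `optimization_report`.
#' @param format `"json"` or `"markdown"`.
#' @param ds The dataset the report was computed from; required for the
#'   Markdown yield table, ignored for JSON.
#' @return A single string.
#' @examples
#' ds <- load_fixture("table1")
#' cat(substr(report_document(optimize_extraction(ds), "json"), 1, 200))
#' @export
report_document <- function(rep, format = c("json", "markdown"), ds = NULL) {
  stopifnot(inherits(rep, "optimization_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  if (is.null(ds)) abort("Markdown rendering needs the source `ds`.")
  stopifnot(inherits(ds, "extraction_dataset"))
  lines <- c("# Extraction optimization report", "")
  lines <- c(lines, sprintf(
    "Consensus optimum: **%g degC, %g%% v/v** (argmax for %d response(s)).",
    rep$consensus$temperature_C, rep$consensus$concentration_pct,
    rep$consensus$n_responses_maximal
  ), "")
  c_levels <- attr(ds, "concentration_levels")
  t_levels <- attr(ds, "temperature_levels")
  for (r in rep$responses) {
    u <- rep$units[[r]]
    lines <- c(lines, sprintf("## %s%s", r, if (u == "") "" else paste0(" (", u, ")")), "")
    header <- paste0("| C, % v/v | ", paste(sprintf("%g degC", t_levels),
                                            collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---|", length(t_levels) + 1L), collapse = ""))
    opt <- rep$optima[rep$optima$response == r, ]
    rows <- vapply(c_levels, function(cc) {
      cells <- vapply(t_levels, function(tt) {
        i <- which(ds$temperature_C == tt & ds$concentration_pct == cc)
        star <- if (tt == opt$temperature_C && cc == opt$concentration_pct) "*" else ""
        sprintf("%.2f ± %.2f%s", ds[[paste0(r, "_mean")]][i],
                ds[[paste0(r, "_sd")]][i], star)
      }, character(1))
      paste0("| ", cc, " | ", paste(cells, collapse = " | "), " |")
    }, character(1))
    lines <- c(lines, header, sep, rows, "")
  }
  lines <- c(lines, "## Fold-changes", "",
             "| response | numerator | denominator | ratio |", "|---|---|---|---|",
             sprintf("| %s | (%g, %g) | (%g, %g) | %.2f |",
                     rep$fold_changes$response,
                     rep$fold_changes$num_temperature_C,
                     rep$fold_changes$num_concentration_pct,
                     rep$fold_changes$den_temperature_C,
                     rep$fold_changes$den_concentration_pct,
                     rep$fold_changes$fold_change), "")
  if (!is.null(rep$refined)) {
    lines <- c(lines, "## Curve-refined maxima (exploratory)", "",
               "| response | s | t | C | value |", "|---|---|---|---|---|",
               sprintf("| %s | %.4f | %.3f | %.3f | %.4f |",
                       rep$refined$response, rep$refined$s,
                       rep$refined$temperature_C,
                       rep$refined$concentration_pct, rep$refined$value), "")
  }
  paste(lines, collapse = "\n")
}
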