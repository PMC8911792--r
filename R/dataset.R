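#' Build a validated factorial extraction dataset
#'
#' An `extraction_dataset` holds a full-factorial solid-liquid extraction
#' experiment: one row per condition (extraction temperature in degrees C
#' crossed with ethanol concentration in % v/v) and, per response, the mean
#' and standard deviation over replicate extractions. The canonical responses
#' are the four bioactive-compound yields TPC, TFC, TC and TAC (total
#' polyphenol, flavonoid, tannin and anthocyanin content), but any set of
#' non-negative responses is accepted.
#'
#' Rows are stored temperature-major (temperature ascending, then
#' concentration ascending) and factor levels sorted ascending. The design
#' must be complete: every temperature level crossed with every concentration
#' level exactly once.
#'
#' @param data A data frame with columns `temperature_C`,
#'   `concentration_pct`, and for each response `<name>_mean` plus optionally
#'   `<name>_sd`. Missing `_sd` columns are filled with 0 (with a warning).
#' @param units Named character vector or list mapping response names to unit
#'   strings (e.g. `c(TPC = "mg GAE/g DW")`). Unspecified units default to
#'   `""`.
#' @return An object of class `extraction_dataset`: the ordered wide tibble
#'   with attributes `responses`, `units`, `temperature_levels` and
#'   `concentration_levels`.
#' @examples
#' ds <- load_fixture("table1")
#' ds
#' extraction_responses(ds)
#' @export
extraction_dataset <- function(data, units = NULL) {
  data <- tibble::as_tibble(data)
  for (col in c("temperature_C", "concentration_pct")) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` is missing from the dataset.", col))
    }
  }
  mean_cols <- grep("_mean$", names(data), value = TRUE)
  if (length(mean_cols) == 0L) {
    abort("No response columns found (expected `<response>_mean`).")
  }
  resp <- sub("_mean$", "", mean_cols)

  missing_sd <- resp[!paste0(resp, "_sd") %in% names(data)]
  if (length(missing_sd) > 0L) {
    warn(sprintf(
      "No `_sd` column for %s; standard deviations set to 0.",
      paste0(missing_sd, collapse = ", ")
    ))
    for (r in missing_sd) data[[paste0(r, "_sd")]] <- 0
  }

  if (nrow(data) == 0L) abort("Dataset has no conditions.")
  if (anyNA(data[c("temperature_C", "concentration_pct")])) {
    abort("Factor columns contain missing values.")
  }
  if (any(data$temperature_C <= 0)) abort("Temperatures must be positive (degrees C).")
  if (any(data$concentration_pct < 0 | data$concentration_pct > 96)) {
    abort("Ethanol concentrations must lie in [0, 96] % v/v.")
  }

  t_levels <- sort(unique(data$temperature_C))
  c_levels <- sort(unique(data$concentration_pct))
  key <- paste(data$temperature_C, data$concentration_pct)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate conditions: %s.",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  if (nrow(data) != length(t_levels) * length(c_levels)) {
    abort(sprintf(
      paste0(
        "Design is not full factorial: %d conditions but %d temperature ",
        "level(s) x %d concentration level(s) = %d expected."
      ),
      nrow(data), length(t_levels), length(c_levels),
      length(t_levels) * length(c_levels)
    ))
  }

  bad <- character(0)
  for (r in resp) {
    m <- data[[paste0(r, "_mean")]]
    s <- data[[paste0(r, "_sd")]]
    for (i in which(!is.finite(m) | m < 0)) {
      bad <- c(bad, sprintf("%s_mean at (%g degC, %g%%)", r,
                            data$temperature_C[i], data$concentration_pct[i]))
    }
    for (i in which(!is.finite(s) | s < 0)) {
      bad <- c(bad, sprintf("%s_sd at (%g degC, %g%%)", r,
                            data$temperature_C[i], data$concentration_pct[i]))
    }
  }
  if (length(bad) > 0L) {
    abort(paste0("Invalid response cells (must be finite and >= 0): ",
                 paste(bad, collapse = "; ")))
  }

  u <- setNames(rep("", length(resp)), resp)
  if (!is.null(units)) {
    units <- unlist(units)
    known <- intersect(names(units), resp)
    u[known] <- units[known]
  }

  ord <- order(data$temperature_C, data$concentration_pct)
  data <- data[ord, c("temperature_C", "concentration_pct",
                      as.vector(rbind(paste0(resp, "_mean"), paste0(resp, "_sd"))))]
  structure(
    data,
    responses = resp,
    units = u,
    temperature_levels = t_levels,
    concentration_levels = c_levels,
    class = c("extraction_dataset", class(data))
  )
}

#' @export
print.extraction_dataset <- function(x, ...) {
  cat(sprintf(
    "<extraction_dataset> %d conditions (%d temperatures x %d concentrations)\n",
    nrow(x), length(attr(x, "temperature_levels")),
    length(attr(x, "concentration_levels"))
  ))
  u <- attr(x, "units")
  cat("responses:",
      paste(sprintf("%s [%s]", names(u), ifelse(u == "", "-", u)), collapse = ", "),
      "\n")
  NextMethod()
  invisible(x)
}

#' Response names of an extraction dataset
#'
#' @param ds An `extraction_dataset`.
#' @return Character vector of response names.
#' @export
extraction_responses <- function(ds) {
  stopifnot(inherits(ds, "extraction_dataset"))
  attr(ds, "responses")
}

#' Measurement units of an extraction dataset
#'
#' @param ds An `extraction_dataset`.
#' @return Named character vector mapping response name to unit string.
#' @export
extraction_units <- function(ds) {
  stopifnot(inherits(ds, "extraction_dataset"))
  attr(ds, "units")
}

resp_or_stop <- function(ds, response) {
  if (!response %in% extraction_responses(ds)) {
    abort(sprintf("Response `%s` not in dataset (have: %s).", response,
                  paste(extraction_responses(ds), collapse = ", ")))
  }
  response
}

condition_row <- function(ds, condition) {
  if (length(condition) != 2L || !is.numeric(condition)) {
    abort("A condition is a numeric pair c(temperature_C, concentration_pct).")
  }
  i <- which(ds$temperature_C == condition[[1]] &
               ds$concentration_pct == condition[[2]])
  if (length(i) != 1L) {
    abort(sprintf("Condition (%g degC, %g%% v/v) is not in the dataset.",
                  condition[[1]], condition[[2]]))
  }
  i
}

#' Write / read an extraction dataset as CSV with a JSON units sidecar
#'
#' The CSV dialect is one row per condition with columns `temperature_C`,
#' `concentration_pct` and `<response>_mean`/`<response>_sd`. Units travel in
#' a sidecar JSON file next to the CSV (same path with extension `.json`),
#' so the numeric table stays plain.
#'
#' @param ds An `extraction_dataset`.
#' @param path CSV file path.
#' @return `write_extraction_csv()` returns `path` invisibly;
#'   `read_extraction_csv()` returns a validated `extraction_dataset`.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_extraction_csv(load_fixture("table1"), tmp)
#' read_extraction_csv(tmp)
#' @export
write_extraction_csv <- function(ds, path) {
  stopifnot(inherits(ds, "extraction_dataset"))
  readr::write_csv(tibble::as_tibble(ds), path)
  sidecar <- paste0(sub("\\.csv$", "", path), ".json")
  jsonlite::write_json(
    list(units = as.list(extraction_units(ds))),
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_extraction_csv
#' @export
read_extraction_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(sub("\\.csv$", "", path), ".json")
  units <- NULL
  if (file.exists(sidecar)) {
    units <- unlist(jsonlite::read_json(sidecar)$units)
  }
  extraction_dataset(data, units = units)
}

#' Load a packaged experiment table
#'
#' Three fixtures ship with the package, transcribed from a factorial
#' grape-marc extraction study: `"table1"` is the 5 x 3 factorial yield
#' table (ethanol concentration 0/40/60/80/96 % v/v crossed with 30/45/65
#' degC; responses TPC, TFC, TC, TAC as mean +/- sd of three extractions);
#' `"table2"` is the composition profile of the optimal extract (individual
#' polyphenols, anthocyanins, organic acids, DPPH/ABTS antioxidant activity
#' and CIELab colour parameters); `"table3"` holds antimicrobial records
#' (inhibition-zone diameters, MIC and MBC) for four bacterial strains, with
#' "no detected activity" stored as missing, never as zero.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`.
#' @return For `"table1"` an [extraction_dataset()]; for `"table2"` a
#'   `composition_profile` tibble (`analyte`, `class`, `mean`, `sd`, `unit`);
#'   for `"table3"` a tibble of antimicrobial records.
#' @examples
#' load_fixture("table1")
#' load_fixture("table3")
#' @export
load_fixture <- function(table_id = c("table1", "table2", "table3")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", paste0(table_id, ".csv"), package = "marcex",
                      mustWork = TRUE)
  switch(
    table_id,
    table1 = read_extraction_csv(path),
    table2 = composition_profile(
      readr::read_csv(path, show_col_types = FALSE,
                      locale = readr::locale(encoding = "UTF-8"))
    ),
    table3 = antimicrobial_records(
      readr::read_csv(path, show_col_types = FALSE)
    )
  )
}

#' Validate a composition profile
#'
#' A composition profile lists named analytes with their class, mean
#' quantity, standard deviation and unit. Analyte names must be unique
#' within a class and quantities non-negative; CIELab entries (class
#' `"chromatic"`) are exempt from the non-negativity rule because the a*/b*
#' opponent components may be negative in general.
#'
#' @param data Data frame with columns `analyte`, `class`, `mean`, `sd`,
#'   `unit`.
#' @return A `composition_profile` tibble.
#' @export
composition_profile <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("analyte", "class", "mean", "sd", "unit")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(paste0("Composition profile is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  dup <- duplicated(data[c("class", "analyte")])
  if (any(dup)) {
    abort(paste0("Duplicate analyte within class: ",
                 paste(data$analyte[dup], collapse = ", ")))
  }
  quant <- data$class != "chromatic"
  if (any(quant & (!is.finite(data$mean) | data$mean < 0))) {
    abort("Quantity means must be finite and >= 0.")
  }
  if (any(is.finite(data$sd) & data$sd < 0)) abort("Standard deviations must be >= 0.")
  class(data) <- c("composition_profile", class(data))
  data
}

#' Validate antimicrobial susceptibility records
#'
#' @param data Data frame with columns `strain`, `gram`
#'   (`"positive"`/`"negative"`), `zone_mean_mm`, `zone_sd_mm`, and optional
#'   `mic_mean_mg_ml`, `mic_sd_mg_ml`, `mbc_mean_mg_ml`, `mbc_sd_mg_ml`
#'   (`NA` = no detected activity).
#' @return The validated tibble (invariant: where both are present,
#'   MBC >= MIC).
#' @export
antimicrobial_records <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("strain", "gram", "zone_mean_mm", "zone_sd_mm")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(paste0("Antimicrobial records missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(data$gram %in% c("positive", "negative"))) {
    abort("`gram` must be \"positive\" or \"negative\".")
  }
  if (all(c("mic_mean_mg_ml", "mbc_mean_mg_ml") %in% names(data))) {
    both <- !is.na(data$mic_mean_mg_ml) & !is.na(data$mbc_mean_mg_ml)
    if (any(both & data$mbc_mean_mg_ml < data$mic_mean_mg_ml)) {
      abort("MBC must be >= MIC wherever both are measured.")
    }
  }
  data
}

#' Extremal extraction condition for a response
#'
#' Finds the condition whose mean response is maximal (or minimal). Ties are
#' broken deterministically by lower temperature, then lower concentration.
#'
#' @param ds An `extraction_dataset`.
#' @param response Response name, e.g. `"TPC"`.
#' @param which `"max"` or `"min"`.
#' @return One-row tibble: `temperature_C`, `concentration_pct`, `mean`,
#'   `sd`.
#' @examples
#' extreme_condition(load_fixture("table1"), "TPC", "max")
#' @export
extreme_condition <- function(ds, response, which = c("max", "min")) {
  stopifnot(inherits(ds, "extraction_dataset"))
  which <- match.arg(which)
  resp_or_stop(ds, response)
  m <- ds[[paste0(response, "_mean")]]
  target <- if (which == "max") max(m) else min(m)
  cand <- which(m == target)
  # rows are temperature-major sorted, so the first candidate is the tie-break
  i <- cand[[1]]
  tibble::tibble(
    temperature_C = ds$temperature_C[i],
    concentration_pct = ds$concentration_pct[i],
    mean = m[i],
    sd = ds[[paste0(response, "_sd")]][i]
  )
}

#' Yield fold-change between two conditions
#'
#' Ratio of mean response at `cond_num` over `cond_den`, rounded half-up.
#' Raising the extraction temperature from 30 to 65 degC at 60 % v/v ethanol
#' multiplies the four yields by 1.47 (TPC), 1.59 (TFC), 1.63 (TC) and 1.45
#' (TAC) in the packaged fixture.
#'
#' @param ds An `extraction_dataset`.
#' @param response Response name.
#' @param cond_num,cond_den Numeric pairs `c(temperature_C,
#'   concentration_pct)`; both must be measured conditions.
#' @param decimals Decimal places for half-up rounding (default 2).
#' @return A single dimensionless ratio.
#' @examples
#' fold_change(load_fixture("table1"), "TPC", c(65, 60), c(30, 60))
#' @export
fold_change <- function(ds, response, cond_num, cond_den, decimals = 2) {
  stopifnot(inherits(ds, "extraction_dataset"))
  resp_or_stop(ds, response)
  m <- ds[[paste0(response, "_mean")]]
  num <- m[condition_row(ds, cond_num)]
  den <- m[condition_row(ds, cond_den)]
  if (den == 0) abort("Denominator condition has zero mean; fold-change undefined.")
  round_half_up(num / den, decimals)
}

#' Two-fold dilution series
#'
#' Concentration fractions of a broth macro-dilution series: the starting
#' fraction is halved tube by tube, as in MIC/MBC determination where a 50 %
#' extract in tube 1 becomes 25 % in tube 2 and so on.
#'
#' @param start_fraction Starting concentration fraction in (0, 1].
#' @param n_tubes Number of tubes (>= 1).
#' @return Numeric vector of length `n_tubes`:
#'   `start_fraction / 2^(0:(n_tubes-1))`.
#' @examples
#' dilution_series(0.5, 10)
#' @export
dilution_series <- function(start_fraction, n_tubes) {
  check_scalar_number(start_fraction, "start_fraction", positive = TRUE)
  if (start_fraction > 1) abort("`start_fraction` must lie in (0, 1].")
  if (!is.numeric(n_tubes) || length(n_tubes) != 1L || n_tubes < 1 ||
      n_tubes != as.integer(n_tubes)) {
    abort("`n_tubes` must be a positive integer.")
  }
  start_fraction / 2^(seq_len(n_tubes) - 1)
}

#' Summarise one class of a composition profile
#'
#' Totals the mean quantities of a class and ranks analytes by their share
#' of that total (shares sum to one).
#'
#' @param profile A `composition_profile` (see [load_fixture()]).
#' @param class Class name present in the profile, e.g. `"anthocyanin"`.
#' @return List with `class`, `unit`, `total` and `table` (tibble `analyte`,
#'   `mean`, `sd`, `share`, ranked descending by mean).
#' @examples
#' composition_summary(load_fixture("table2"), "anthocyanin")
#' @export
composition_summary <- function(profile, class) {
  stopifnot(inherits(profile, "composition_profile"))
  sub <- profile[profile$class == class, ]
  if (nrow(sub) == 0L) {
    abort(sprintf("Class `%s` not present in the profile.", class))
  }
  total <- sum(sub$mean)
  if (total <= 0) abort("Class total is zero; shares undefined.")
  out <- sub[order(-sub$mean), c("analyte", "mean", "sd")]
  out$share <- out$mean / total
  list(
    class = class,
    unit = unique(sub$unit)[[1]],
    total = total,
    table = tibble::as_tibble(out)
  )
}
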