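#' Configuration for the synthetic factorial generator
#'
#' Describes a simulated solid-liquid extraction experiment with the
#' statistical structure the analysis pipeline assumes: a yield surface that
#' is unimodal in ethanol concentration (Gaussian peak at `c0`, width `w`)
#' and increases linearly with temperature (slope `beta`), Gaussian
#' measurement noise, and a tunable cross-response coupling. The mean
#' surface is `mu(t, C) = y0 + beta * t * exp(-(C - c0)^2 / (2 w^2))` and an
#' observed replicate is `mu + rho * sigma * Z + sqrt(1 - rho^2) * sigma *
#' eps`, where `Z` is a latent standard-normal draw shared by all responses
#' of a condition/replicate (weight `rho` makes responses co-fluctuate) and
#' `eps` is independent noise. Defaults mirror the packaged factorial
#' experiment: temperatures 30/45/65 degC, concentrations 0/40/60/80/96 %
#' v/v, peak at 60 % v/v, three replicates, and per-response scales chosen
#' so the noise-free surface peaks near the fixture's yields.
#'
#' @param temperature_levels Distinct positive temperatures (degC).
#' @param concentration_levels Distinct ethanol concentrations in `[0, 96]`.
#' @param responses Named list; each element a list with `y0` (baseline),
#'   `beta` (response units per degC), `c0` (peak concentration, % v/v),
#'   `w` (peak width, % v/v), `sigma` (replicate noise sd, response units).
#' @param rho Cross-response coupling weight in `[0, 1]`.
#' @param replicates Replicate extractions per condition (>= 1).
#' @param seed Integer RNG seed.
#' @return A `synthetic_config` list.
#' @examples
#' synthetic_config(rho = 0.5, seed = 42)
#' @export
synthetic_config <- function(temperature_levels = c(30, 45, 65),
                             concentration_levels = c(0, 40, 60, 80, 96),
                             responses = list(
                               TPC = list(y0 = 1.2, beta = 0.150, c0 = 60, w = 30, sigma = 0.15),
                               TFC = list(y0 = 0.8, beta = 0.107, c0 = 60, w = 30, sigma = 0.10),
                               TC  = list(y0 = 0.10, beta = 0.020, c0 = 60, w = 30, sigma = 0.03),
                               TAC = list(y0 = 0.05, beta = 0.014, c0 = 60, w = 30, sigma = 0.01)
                             ),
                             rho = 0,
                             replicates = 3,
                             seed = 1) {
  problems <- character(0)
  if (length(temperature_levels) == 0L || anyDuplicated(temperature_levels) ||
      any(temperature_levels <= 0)) {
    problems <- c(problems, "temperature_levels must be distinct and positive")
  }
  if (length(concentration_levels) == 0L || anyDuplicated(concentration_levels) ||
      any(concentration_levels < 0 | concentration_levels > 96)) {
    problems <- c(problems, "concentration_levels must be distinct and in [0, 96]")
  }
  if (length(responses) == 0L || is.null(names(responses)) ||
      any(names(responses) == "")) {
    problems <- c(problems, "responses must be a non-empty named list")
  } else {
    for (r in names(responses)) {
      p <- responses[[r]]
      miss <- setdiff(c("y0", "beta", "c0", "w", "sigma"), names(p))
      if (length(miss) > 0L) {
        problems <- c(problems, sprintf("response %s missing field(s) %s", r,
                                        paste(miss, collapse = ", ")))
      } else if (p$sigma < 0 || p$w <= 0) {
        problems <- c(problems, sprintf("response %s needs sigma >= 0 and w > 0", r))
      }
    }
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    problems <- c(problems, "rho must lie in [0, 1]")
  }
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1 ||
      replicates != as.integer(replicates)) {
    problems <- c(problems, "replicates must be a positive integer")
  }
  if (length(problems) > 0L) {
    abort(paste0("Invalid synthetic configuration: ",
                 paste(problems, collapse = "; "), "."))
  }
  structure(
    list(
      temperature_levels = sort(temperature_levels),
      concentration_levels = sort(concentration_levels),
      responses = responses,
      rho = rho,
      replicates = as.integer(replicates),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

surface_mean <- function(t, C, p) {
  p$y0 + p$beta * t * exp(-(C - p$c0)^2 / (2 * p$w^2))
}

#' Generate a synthetic factorial extraction dataset
#'
#' Simulates replicate observations on the full factorial grid of the
#' configuration (see [synthetic_config()] for the surface and noise
#' model), stores replicate means and standard deviations as a validated
#' [extraction_dataset()], and returns the design ground truth alongside.
#' Observations are truncated at zero, as measured contents cannot be
#' negative. Fully reproducible from the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (an `extraction_dataset`), `truth` (tibble:
#'   per-response `c0`, `beta`, and the noise-free argmax condition) and
#'   `config`.
#' @examples
#' sim <- generate_extraction(synthetic_config(seed = 7))
#' sim$dataset
#' sim$truth
#' @export
generate_extraction <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- expand.grid(
    concentration_pct = config$concentration_levels,
    temperature_C = config$temperature_levels
  )[, 2:1]
  n_cond <- nrow(grid)
  resp <- names(config$responses)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  # shared latent draws first, then per-response noise: the same seed yields
  # the same underlying draws for every coupling weight rho
  Z <- matrix(rnorm(n_cond * config$replicates), n_cond, config$replicates)
  eps <- lapply(setNames(resp, resp), function(r) {
    matrix(rnorm(n_cond * config$replicates), n_cond, config$replicates)
  })

  data <- tibble::as_tibble(grid)
  for (r in resp) {
    p <- config$responses[[r]]
    mu <- surface_mean(grid$temperature_C, grid$concentration_pct, p)
    obs <- mu + config$rho * p$sigma * Z +
      sqrt(1 - config$rho^2) * p$sigma * eps[[r]]
    obs <- pmax(obs, 0)
    data[[paste0(r, "_mean")]] <- rowMeans(obs)
    data[[paste0(r, "_sd")]] <- if (config$replicates > 1L) {
      apply(obs, 1, stats::sd)
    } else {
      rep(0, n_cond)
    }
  }

  truth <- dplyr::bind_rows(lapply(resp, function(r) {
    p <- config$responses[[r]]
    c_star <- config$concentration_levels[
      which.min(abs(config$concentration_levels - p$c0))
    ]
    tibble::tibble(
      response = r, c0 = p$c0, beta = p$beta,
      argmax_temperature_C = max(config$temperature_levels),
      argmax_concentration_pct = c_star
    )
  }))

  list(
    dataset = extraction_dataset(data),
    truth = truth,
    config = config
  )
}

#' Parameter-recovery suite over a grid of configurations
#'
#' For each configuration: generates a dataset, checks whether the
#' per-response argmax over measured conditions recovers the designed
#' optimum, fits the cubic parametric curve per response and records the
#' maximum knot residual, and checks the mutual-information ordering
#' (strongest response-response edge exceeds the strongest
#' temperature-response edge at the default discretization). Aggregates the
#' argmax recovery rate with its 95 % Wilson score interval.
#'
#' @param configs List of [synthetic_config()] objects.
#' @return List with `table` (one row per config: `seed`, `rho`,
#'   `argmax_recovered`, `max_knot_residual`, `mi_ordering_holds`) and
#'   `summary` (recovery rate with Wilson interval).
#' @examples
#' cfgs <- lapply(1:3, function(s) synthetic_config(seed = s))
#' recovery_suite(cfgs)$summary
#' @export
recovery_suite <- function(configs) {
  if (length(configs) == 0L) abort("`configs` must be a non-empty list.")
  rows <- lapply(configs, function(cfg) {
    stopifnot(inherits(cfg, "synthetic_config"))
    sim <- generate_extraction(cfg)
    ds <- sim$dataset
    resp <- extraction_responses(ds)

    recovered <- all(vapply(resp, function(r) {
      got <- extreme_condition(ds, r, "max")
      tr <- sim$truth[sim$truth$response == r, ]
      got$temperature_C == tr$argmax_temperature_C &&
        got$concentration_pct == tr$argmax_concentration_pct
    }, logical(1)))

    res <- max(vapply(resp, function(r) {
      pts <- order_points(ds, r)
      knot_residuals(fit_parametric_spline(pts), pts)$max_relative
    }, numeric(1)))

    g <- dependency_graph(ds)
    rr <- utils::combn(resp, 2, simplify = FALSE)
    mi_resp <- max(vapply(rr, function(p) graph_edge(g, p[[1]], p[[2]]),
                          numeric(1)))
    mi_temp <- max(vapply(resp, function(r) graph_edge(g, "temperature", r),
                          numeric(1)))

    tibble::tibble(
      seed = cfg$seed,
      rho = cfg$rho,
      argmax_recovered = recovered,
      max_knot_residual = res,
      mi_ordering_holds = mi_resp > mi_temp
    )
  })
  table <- dplyr::bind_rows(rows)
  wi <- wilson_interval(sum(table$argmax_recovered), nrow(table))
  list(
    table = table,
    summary = tibble::tibble(
      n_configs = nrow(table),
      recovery_rate = wi[["estimate"]],
      recovery_lower = wi[["lower"]],
      recovery_upper = wi[["upper"]],
      max_knot_residual = max(table$max_knot_residual),
      mi_ordering_rate = mean(table$mi_ordering_holds)
    )
  )
}
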