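#' Order factorial grid points into a single traversal
#'
#' The piecewise-curve model threads one parametric curve through all
#' experimental points, so the 2-D factorial grid must first be flattened
#' into an ordered sequence of `(t, C, response)` triples. Two traversals
#' are offered: `"lexicographic"` (temperature-major, concentration
#' ascending within each temperature block) and `"serpentine"`
#' (concentration direction alternates between consecutive temperature
#' blocks, so the curve never jumps back across the concentration range).
#'
#' @param ds An [extraction_dataset()].
#' @param response Response name whose means form the third coordinate.
#' @param scheme `"lexicographic"` or `"serpentine"`.
#' @return Tibble with columns `t` (degC), `C` (% v/v), `response`
#'   (response units), one row per condition, in traversal order. Attributes
#'   `scheme` and `response_name` record the provenance.
#' @examples
#' head(order_points(load_fixture("table1"), "TPC", "lexicographic"))
#' @export
order_points <- function(ds, response, scheme = c("lexicographic", "serpentine")) {
  stopifnot(inherits(ds, "extraction_dataset"))
  scheme <- match.arg(scheme)
  resp_or_stop(ds, response)

  tbl <- tibble::tibble(
    t = ds$temperature_C,
    C = ds$concentration_pct,
    response = ds[[paste0(response, "_mean")]]
  )
  tbl <- tbl[order(tbl$t, tbl$C), ]
  if (scheme == "serpentine") {
    t_levels <- sort(unique(tbl$t))
    blocks <- lapply(seq_along(t_levels), function(b) {
      block <- tbl[tbl$t == t_levels[[b]], ]
      if (b %% 2 == 0) block <- block[rev(seq_len(nrow(block))), ]
      block
    })
    tbl <- dplyr::bind_rows(blocks)
  }
  attr(tbl, "scheme") <- scheme
  attr(tbl, "response_name") <- response
  tbl
}

# One-dimensional interpolating piecewise polynomial on strictly increasing
# knots xi. Returns an (n-1) x (k+1) coefficient matrix in descending local
# powers: value on [xi_i, xi_{i+1}] is sum_j coef[i, j] * (x - xi_i)^(k+1-j).
piecewise_poly_coefs <- function(xi, y, k, boundary) {
  n <- length(xi)
  h <- diff(xi)
  if (any(h <= 0)) abort("Knot parameter values must be strictly increasing.")
  if (k == 1) {
    return(cbind(diff(y) / h, y[-n], deparse.level = 0))
  }
  # cubic: solve for second derivatives M at the knots
  if (n == 2) {
    M <- c(0, 0)
    if (boundary == "not_a_knot") {
      abort("The not-a-knot boundary needs at least 4 points.")
    }
  } else {
    A <- matrix(0, n, n)
    rhs <- numeric(n)
    for (i in 2:(n - 1)) {
      A[i, i - 1] <- h[i - 1]
      A[i, i] <- 2 * (h[i - 1] + h[i])
      A[i, i + 1] <- h[i]
      rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
    if (boundary == "natural") {
      A[1, 1] <- 1
      A[n, n] <- 1
    } else { # not_a_knot: third derivative continuous at the 2nd and (n-1)th knot
      if (n < 4) abort("The not-a-knot boundary needs at least 4 points.")
      A[1, 1:3] <- c(-h[2], h[1] + h[2], -h[1])
      A[n, (n - 2):n] <- c(-h[n - 1], h[n - 2] + h[n - 1], -h[n - 2])
    }
    M <- solve(A, rhs)
  }
  i <- seq_len(n - 1)
  a <- y[i]
  b <- (y[i + 1] - y[i]) / h - h * (2 * M[i] + M[i + 1]) / 6
  cc <- M[i] / 2
  d <- (M[i + 1] - M[i]) / (6 * h)
  cbind(d, cc, b, a, deparse.level = 0)
}

#' Fit a parametric piecewise polynomial curve through ordered points
#'
#' Fits one interpolating spline of order `k` per direction (`t`, `C`,
#' `response`) against a shared knot parameter, yielding a single 3-D curve
#' that passes through every experimental point. For a cubic (`k = 3`) each
#' of the `n - 1` intervals carries `k + 1 = 4` local coefficients per
#' direction, so a 15-point experiment yields `(15 - 1) x 3 x 4 = 168`
#' coefficients in total. The local polynomial on interval `i` is
#' `sum_j c_ji (s - xi_i)^(k+1-j)`.
#'
#' @param points Ordered tibble of `(t, C, response)` triples, typically
#'   from [order_points()].
#' @param k Spline order: 3 (cubic, default) or 1 (piecewise linear).
#' @param parameterization `"index"` (knots at 0, 1, ..., n-1; default) or
#'   `"chord"` (cumulative Euclidean chord length in `(t, C, response)`
#'   space).
#' @param boundary `"natural"` (zero second derivative at both ends;
#'   default) or `"not_a_knot"`. Cubic only.
#' @return A `piecewise_curve`: list with `knots`, `order`, `boundary`,
#'   `parameterization`, `pieces` (per-direction coefficient matrices in
#'   descending local powers) and the input `points`.
#' @examples
#' pts <- order_points(load_fixture("table1"), "TPC")
#' crv <- fit_parametric_spline(pts)
#' crv
#' @export
fit_parametric_spline <- function(points,
                                  k = 3,
                                  parameterization = c("index", "chord"),
                                  boundary = c("natural", "not_a_knot")) {
  parameterization <- match.arg(parameterization)
  boundary <- match.arg(boundary)
  if (!k %in% c(1, 3)) abort("Spline order `k` must be 1 (linear) or 3 (cubic).")
  points <- tibble::as_tibble(points)
  need <- c("t", "C", "response")
  if (!all(need %in% names(points))) {
    abort("`points` must have columns t, C and response.")
  }
  n <- nrow(points)
  if (n < 2) abort("At least 2 points are needed to fit a curve.")

  if (parameterization == "index") {
    xi <- as.numeric(seq_len(n) - 1)
  } else {
    step <- sqrt(diff(points$t)^2 + diff(points$C)^2 + diff(points$response)^2)
    if (any(step == 0)) {
      abort("Chord-length parameterization requires consecutive points to differ.")
    }
    xi <- c(0, cumsum(step))
  }

  pieces <- lapply(
    setNames(need, need),
    function(dir) piecewise_poly_coefs(xi, points[[dir]], k, boundary)
  )
  structure(
    list(
      knots = xi,
      order = k,
      boundary = boundary,
      parameterization = parameterization,
      scheme = attr(points, "scheme") %||% NA_character_,
      response_name = attr(points, "response_name") %||% NA_character_,
      pieces = pieces,
      points = points
    ),
    class = "piecewise_curve"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.piecewise_curve <- function(x, ...) {
  n <- length(x$knots)
  cat(sprintf(
    paste0(
      "<piecewise_curve> order k = %d, %d knots, %d intervals, ",
      "%d coefficients (3 directions x %d x %d)\n"
    ),
    x$order, n, n - 1, (n - 1) * 3 * (x$order + 1), n - 1, x$order + 1
  ))
  cat(sprintf("parameterization: %s; boundary: %s; point ordering: %s\n",
              x$parameterization, x$boundary, x$scheme))
  invisible(x)
}

piece_index <- function(knots, s) {
  n <- length(knots)
  i <- findInterval(s, knots, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), n - 1L)
}

#' Evaluate a parametric curve
#'
#' Evaluates all three directions at parameter values `s`. Intervals are
#' right-open with the last interval closed; values outside the knot range
#' are refused unless `extrapolate = TRUE` (extrapolation extends the first
#' or last polynomial piece).
#'
#' @param curve A `piecewise_curve`.
#' @param s Numeric vector of parameter values.
#' @param extrapolate Allow evaluation outside `[min(knots), max(knots)]`?
#'   Default `FALSE`.
#' @return Tibble with columns `s`, `t`, `C`, `response`.
#' @examples
#' crv <- fit_parametric_spline(order_points(load_fixture("table1"), "TPC"))
#' evaluate_curve(crv, crv$knots)
#' @export
evaluate_curve <- function(curve, s, extrapolate = FALSE) {
  stopifnot(inherits(curve, "piecewise_curve"))
  if (!is.numeric(s) || anyNA(s)) abort("`s` must be numeric with no missing values.")
  kn <- curve$knots
  if (!extrapolate && (any(s < kn[[1]]) || any(s > kn[[length(kn)]]))) {
    abort(sprintf(
      "Parameter values outside [%g, %g]; set `extrapolate = TRUE` to allow.",
      kn[[1]], kn[[length(kn)]]
    ))
  }
  i <- piece_index(kn, s)
  dx <- s - kn[i]
  p <- curve$order + 1L
  eval_dir <- function(coefs) {
    acc <- numeric(length(s))
    for (j in seq_len(p)) acc <- acc * dx + coefs[i, j]
    acc
  }
  tibble::tibble(
    s = s,
    t = eval_dir(curve$pieces$t),
    C = eval_dir(curve$pieces$C),
    response = eval_dir(curve$pieces$response)
  )
}

#' Export and re-import local polynomial coefficients
#'
#' `export_coefficients()` flattens a fitted curve into a long table with
#' one row per (direction, interval, coefficient index j); row count is
#' `(n - 1) x 3 x (k + 1)`. `curve_from_coefficients()` rebuilds an
#' evaluable curve from such a table plus the knot sequence, so coefficient
#' tables round-trip losslessly.
#'
#' @param curve A `piecewise_curve`.
#' @return Tibble with columns `direction` (`t`/`C`/`response`), `interval`
#'   (1-based), `j` (1 = leading power), `coefficient`.
#' @examples
#' crv <- fit_parametric_spline(order_points(load_fixture("table1"), "TPC"))
#' nrow(export_coefficients(crv))
#' @export
export_coefficients <- function(curve) {
  stopifnot(inherits(curve, "piecewise_curve"))
  p <- curve$order + 1L
  n1 <- length(curve$knots) - 1L
  dplyr::bind_rows(lapply(c("t", "C", "response"), function(dir) {
    tibble::tibble(
      direction = dir,
      interval = rep(seq_len(n1), each = p),
      j = rep(seq_len(p), times = n1),
      coefficient = as.vector(t(curve$pieces[[dir]]))
    )
  }))
}

#' @rdname export_coefficients
#' @param coefs Long coefficient table as produced by
#'   `export_coefficients()`.
#' @param knots Strictly increasing knot parameter values (length
#'   `max(interval) + 1`).
#' @param order Spline order `k` the table was exported with.
#' @param boundary,parameterization Optional provenance tags carried on the
#'   rebuilt curve.
#' @export
curve_from_coefficients <- function(coefs, knots, order = 3,
                                    boundary = NA_character_,
                                    parameterization = NA_character_) {
  coefs <- tibble::as_tibble(coefs)
  need <- c("direction", "interval", "j", "coefficient")
  if (!all(need %in% names(coefs))) {
    abort("`coefs` must have columns direction, interval, j, coefficient.")
  }
  p <- order + 1L
  n1 <- length(knots) - 1L
  pieces <- lapply(setNames(c("t", "C", "response"), c("t", "C", "response")),
    function(dir) {
      sub <- coefs[coefs$direction == dir, ]
      if (nrow(sub) != n1 * p) {
        abort(sprintf("Direction `%s` has %d rows; expected %d.",
                      dir, nrow(sub), n1 * p))
      }
      sub <- sub[order(sub$interval, sub$j), ]
      matrix(sub$coefficient, nrow = n1, ncol = p, byrow = TRUE)
    })
  crv <- structure(
    list(
      knots = as.numeric(knots),
      order = order,
      boundary = boundary,
      parameterization = parameterization,
      scheme = NA_character_,
      response_name = NA_character_,
      pieces = pieces,
      points = NULL
    ),
    class = "piecewise_curve"
  )
  crv$points <- evaluate_curve(crv, crv$knots)[c("t", "C", "response")]
  crv
}

#' Residuals of a fitted curve at its knots
#'
#' An interpolating spline must reproduce every input point at its knot; the
#' maximum relative residual over all knots and directions quantifies the
#' (virtually zero) modeling error. Relative error is measured against
#' `max(1, |observed|)` so near-zero coordinates do not inflate it.
#'
#' @param curve A `piecewise_curve`.
#' @param points The ordered `(t, C, response)` triples the curve was fitted
#'   to (same row count as knots).
#' @return List with `table` (tibble: `knot`, `direction`, `observed`,
#'   `fitted`, `residual`, `relative`) and `max_relative`.
#' @examples
#' pts <- order_points(load_fixture("table1"), "TPC")
#' knot_residuals(fit_parametric_spline(pts), pts)$max_relative
#' @export
knot_residuals <- function(curve, points) {
  stopifnot(inherits(curve, "piecewise_curve"))
  points <- tibble::as_tibble(points)
  if (nrow(points) != length(curve$knots)) {
    abort(sprintf("Curve has %d knots but %d points supplied.",
                  length(curve$knots), nrow(points)))
  }
  fit <- evaluate_curve(curve, curve$knots)
  tab <- dplyr::bind_rows(lapply(c("t", "C", "response"), function(dir) {
    obs <- points[[dir]]
    pred <- fit[[dir]]
    tibble::tibble(
      knot = seq_along(obs),
      direction = dir,
      observed = obs,
      fitted = pred,
      residual = pred - obs,
      relative = abs(pred - obs) / pmax(1, abs(obs))
    )
  }))
  list(table = tab, max_relative = max(tab$relative))
}

#' Densely sample a curve for plotting or export
#'
#' @param curve A `piecewise_curve`.
#' @param per_interval Samples per interval (default 100).
#' @return Tibble `s`, `t`, `C`, `response` covering the full knot range.
#' @export
sample_curve <- function(curve, per_interval = 100) {
  stopifnot(inherits(curve, "piecewise_curve"))
  kn <- curve$knots
  s <- unique(unlist(lapply(seq_len(length(kn) - 1L), function(i) {
    seq(kn[[i]], kn[[i + 1]], length.out = per_interval + 1L)
  })))
  evaluate_curve(curve, s)
}
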