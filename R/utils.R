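#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), unlike
#' [base::round()]'s round-half-to-even. Yield fold-changes and CIELab
#' chroma/hue are conventionally reported with this rule; 1.465 prints as
#' 1.47, not 1.46.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(1.465, 7.15, 2.5), c(2, 1, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- x * p
  # guard against representation error pushing an exact .5 just below it
  sign(z) * floor(abs(z) + 0.5 + 1e-9 * pmax(1, abs(z))) / p
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector with `estimate`, `lower`, `upper`.
#' @examples
#' wilson_interval(18, 20)
#' @export
wilson_interval <- function(successes, n, conf = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# shared input checks ---------------------------------------------------

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
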