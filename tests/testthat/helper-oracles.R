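# Shared helpers: tiny in-code fixtures and independent oracles.

# A 2 x 2 factorial toy dataset with a single response.
toy_dataset <- function() {
  extraction_dataset(
    data.frame(
      temperature_C = c(30, 30, 65, 65),
      concentration_pct = c(0, 60, 0, 60),
      Y_mean = c(1, 2, 3, 4),
      Y_sd = c(0.1, 0.1, 0.1, 0.1)
    ),
    units = c(Y = "mg/g")
  )
}

# Brute-force natural-cubic oracle: assembles the full 4(n-1)-unknown linear
# system (interpolation at both interval ends, C1/C2 continuity at interior
# knots, zero second derivative at the boundary) and solves it dense. This
# is an independent code path from the tridiagonal second-derivative solve
# used by the package.
brute_force_natural_cubic <- function(xi, y) {
  n <- length(xi)
  m <- 4L * (n - 1L)
  A <- matrix(0, m, m)
  b <- numeric(m)
  row <- 0L
  idx <- function(i) (i - 1L) * 4L + 1:4 # coefficients d, c, b, a of piece i
  for (i in seq_len(n - 1L)) {
    h <- xi[i + 1L] - xi[i]
    row <- row + 1L; A[row, idx(i)] <- c(0, 0, 0, 1); b[row] <- y[i]
    row <- row + 1L; A[row, idx(i)] <- c(h^3, h^2, h, 1); b[row] <- y[i + 1L]
  }
  for (i in seq_len(n - 2L)) {
    h <- xi[i + 1L] - xi[i]
    row <- row + 1L # first-derivative continuity at interior knot i+1
    A[row, idx(i)] <- c(3 * h^2, 2 * h, 1, 0)
    A[row, idx(i + 1L)] <- c(0, 0, -1, 0)
    row <- row + 1L # second-derivative continuity
    A[row, idx(i)] <- c(6 * h, 2, 0, 0)
    A[row, idx(i + 1L)] <- c(0, -2, 0, 0)
  }
  row <- row + 1L; A[row, idx(1L)] <- c(0, 2, 0, 0) # natural left
  h <- xi[n] - xi[n - 1L]
  row <- row + 1L; A[row, idx(n - 1L)] <- c(6 * h, 2, 0, 0) # natural right
  coefs <- solve(A, b)
  matrix(coefs, ncol = 4L, byrow = TRUE) # rows: pieces; cols: d, c, b, a
}

eval_brute_piece <- function(coefs, xi, x) {
  i <- findInterval(x, xi, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(xi) - 1L)
  dx <- x - xi[i]
  coefs[i, 1] * dx^3 + coefs[i, 2] * dx^2 + coefs[i, 3] * dx + coefs[i, 4]
}

# Exact MI of a joint probability matrix by direct summation over all cells.
mi_from_joint <- function(P) {
  stopifnot(abs(sum(P) - 1) < 1e-12)
  pr <- rowSums(P)
  pc <- colSums(P)
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) {
        total <- total + P[i, j] * log2(P[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  total
}

# Draw label pairs whose empirical joint is exactly N * P (P with rational
# entries), so plug-in MI on the sample equals the distribution MI.
labels_from_joint <- function(P, N) {
  counts <- round(P * N)
  stopifnot(sum(counts) == N)
  x <- integer(0)
  y <- integer(0)
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      x <- c(x, rep(i, counts[i, j]))
      y <- c(y, rep(j, counts[i, j]))
    }
  }
  list(x = x, y = y)
}
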