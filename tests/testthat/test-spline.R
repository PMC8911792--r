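test_that("grid traversal schemes order the factorial points as documented", {
  ds <- load_fixture("table1")
  lex <- order_points(ds, "TPC", "lexicographic")
  expect_equal(unlist(lex[1, ], use.names = FALSE), c(30, 0, 3.41))
  expect_equal(unlist(lex[15, ], use.names = FALSE), c(65, 96, 2.39))
  expect_equal(nrow(dplyr::distinct(lex)), 15)

  ser <- order_points(ds, "TPC", "serpentine")
  # second temperature block runs concentration downwards, so it opens at 96
  expect_equal(ser$C[6], 96)
  expect_equal(ser$t[6], 45)
  expect_setequal(paste(ser$t, ser$C), paste(lex$t, lex$C))

  single <- extraction_dataset(data.frame(
    temperature_C = rep(40, 3), concentration_pct = c(0, 40, 80),
    Y_mean = 1:3, Y_sd = 0
  ))
  expect_equal(order_points(single, "Y", "lexicographic"),
               order_points(single, "Y", "serpentine"),
               ignore_attr = TRUE)
})

test_that("coefficient accounting follows (n-1) x 3 x (k+1)", {
  ds <- load_fixture("table1")
  pts <- order_points(ds, "TPC")
  expect_equal(nrow(export_coefficients(fit_parametric_spline(pts, k = 3))), 168)
  expect_equal(nrow(export_coefficients(fit_parametric_spline(pts, k = 1))), 84)
  two <- tibble::tibble(t = c(0, 1), C = c(0, 1), response = c(0, 1))
  expect_equal(nrow(export_coefficients(fit_parametric_spline(two, k = 3))), 12)
  for (n in c(2, 5, 9)) {
    p <- tibble::tibble(t = seq_len(n), C = sqrt(seq_len(n)), response = seq_len(n)^2)
    for (k in c(1, 3)) {
      expect_equal(nrow(export_coefficients(fit_parametric_spline(p, k = k))),
                   (n - 1) * 3 * (k + 1))
    }
  }
})

test_that("fitted curves interpolate every input point at the knots", {
  ds <- load_fixture("table1")
  for (r in extraction_responses(ds)) {
    for (scheme in c("lexicographic", "serpentine")) {
      pts <- order_points(ds, r, scheme)
      for (param in c("index", "chord")) {
        crv <- fit_parametric_spline(pts, parameterization = param)
        expect_lt(knot_residuals(crv, pts)$max_relative, 1e-9)
      }
    }
  }
  # piecewise linear interpolates too
  pts <- order_points(ds, "TPC")
  expect_lt(knot_residuals(fit_parametric_spline(pts, k = 1), pts)$max_relative, 1e-9)
})

test_that("collinear points yield a line: higher-order coefficients vanish", {
  pts <- tibble::tibble(t = 0:3, C = 0:3, response = 0:3)
  crv <- fit_parametric_spline(pts, boundary = "natural")
  co <- export_coefficients(crv)
  expect_true(all(abs(co$coefficient[co$j %in% c(1, 2)]) < 1e-9))
})

test_that("cubic pieces join with continuous value and derivatives", {
  pts <- order_points(load_fixture("table1"), "TPC")
  for (bnd in c("natural", "not_a_knot")) {
    crv <- fit_parametric_spline(pts, boundary = bnd)
    kn <- crv$knots
    for (dir in c("t", "C", "response")) {
      co <- crv$pieces[[dir]]
      for (i in seq_len(length(kn) - 2L)) {
        h <- kn[i + 1] - kn[i]
        # analytic value/derivatives of piece i at its right end vs piece i+1 at 0
        v_l <- co[i, 1] * h^3 + co[i, 2] * h^2 + co[i, 3] * h + co[i, 4]
        d1_l <- 3 * co[i, 1] * h^2 + 2 * co[i, 2] * h + co[i, 3]
        d2_l <- 6 * co[i, 1] * h + 2 * co[i, 2]
        expect_equal(v_l, co[i + 1, 4], tolerance = 1e-8)
        expect_equal(d1_l, co[i + 1, 3], tolerance = 1e-8)
        expect_equal(d2_l, 2 * co[i + 1, 2], tolerance = 1e-8)
      }
    }
  }
})

test_that("tridiagonal fit agrees with independent oracles", {
  # oracle 1: full-constraint dense solve on small inputs
  set.seed(11)
  for (n in 3:6) {
    xi <- as.numeric(0:(n - 1))
    y <- rnorm(n)
    pts <- tibble::tibble(t = xi, C = xi, response = y)
    crv <- fit_parametric_spline(pts, boundary = "natural")
    oracle <- brute_force_natural_cubic(xi, y)
    s <- seq(0, n - 1, length.out = 41)
    expect_equal(evaluate_curve(crv, s)$response, eval_brute_piece(oracle, xi, s),
                 tolerance = 1e-9)
  }
  # oracle 2: stats::splinefun natural spline on the fixture
  pts <- order_points(load_fixture("table1"), "TPC")
  crv <- fit_parametric_spline(pts)
  f <- stats::splinefun(crv$knots, pts$response, method = "natural")
  s <- seq(0, 14, length.out = 201)
  expect_equal(evaluate_curve(crv, s)$response, f(s), tolerance = 1e-9)
})

test_that("evaluation respects the knot range and the piece envelope", {
  pts <- order_points(load_fixture("table1"), "TPC")
  crv <- fit_parametric_spline(pts)
  expect_error(evaluate_curve(crv, -0.5), "extrapolate")
  expect_error(evaluate_curve(crv, 14.5), "extrapolate")
  expect_silent(evaluate_curve(crv, 14.5, extrapolate = TRUE))

  at_knots <- evaluate_curve(crv, crv$knots)
  expect_equal(at_knots$response, pts$response, tolerance = 1e-9)
  expect_equal(at_knots$t[1], 30)

  # interval midpoints lie inside the dense-sampled envelope of their cubic
  for (i in 1:14) {
    dense <- evaluate_curve(crv, seq(i - 1, i, length.out = 2001))$response
    mid <- evaluate_curve(crv, i - 0.5)$response
    expect_gte(mid, min(dense) - 1e-12)
    expect_lte(mid, max(dense) + 1e-12)
  }
})

test_that("exported coefficients round-trip into an equivalent curve", {
  pts <- order_points(load_fixture("table1"), "TPC")
  crv <- fit_parametric_spline(pts)
  co <- export_coefficients(crv)
  back <- curve_from_coefficients(co, crv$knots, order = 3)
  expect_equal(evaluate_curve(back, crv$knots)$response, pts$response,
               tolerance = 1e-9)
  s <- seq(0, 14, length.out = 57)
  expect_equal(evaluate_curve(back, s), evaluate_curve(crv, s), tolerance = 1e-12)
})

test_that("knot residuals flag a perturbed coefficient", {
  pts <- order_points(load_fixture("table1"), "TPC")
  crv <- fit_parametric_spline(pts)
  crv$pieces$response[3, 4] <- crv$pieces$response[3, 4] + 0.5
  expect_gt(knot_residuals(crv, pts)$max_relative, 1e-3)
  expect_error(knot_residuals(crv, pts[-1, ]), "knots")
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  one <- tibble::tibble(t = 1, C = 1, response = 1)
  expect_error(fit_parametric_spline(one), "At least 2")
  dup <- tibble::tibble(t = c(0, 0, 1), C = c(0, 0, 1), response = c(0, 0, 1))
  expect_error(fit_parametric_spline(dup, parameterization = "chord"), "differ")
  three <- tibble::tibble(t = 0:2, C = 0:2, response = c(0, 1, 0))
  expect_error(fit_parametric_spline(three, boundary = "not_a_knot"), "at least 4")
  expect_error(fit_parametric_spline(order_points(load_fixture("table1"), "TPC"), k = 2),
               "order")
})
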