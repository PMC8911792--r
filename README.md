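# marcex

Chemometric analysis of factorial solid–liquid extraction experiments on
grape marc (winemaking pomace). The package is aimed at food-chemistry and
natural-product labs that screen extraction conditions — temperature *t*
(°C) crossed with ethanol concentration *C* (% v/v) — and measure yields of
biologically active compounds: total polyphenols (TPC), flavonoids (TFC),
tannins (TC) and anthocyanins (TAC), each as mean ± sd over replicate
extractions.

It answers three questions about such an experiment:

* **Where is the optimum?** Per-response and consensus argmax over measured
  conditions, minima, and half-up-rounded fold-changes between condition
  pairs (`optimize_extraction()`).
* **What is the exact shape of the yield profile?** A parametric piecewise
  cubic curve threaded through *all* experimental points. On interval *i*
  each direction (t, C, response) follows the local polynomial

  &nbsp;&nbsp;&nbsp;&nbsp;P<sub>i</sub>(x) = Σ<sub>j=1..k+1</sub> c<sub>ji</sub> (x − ξ<sub>i</sub>)<sup>k+1−j</sup>

  with knots ξ<sub>1</sub> < … < ξ<sub>n</sub>, so a cubic (k = 3) on a
  15-point grid carries (15 − 1) × 3 × 4 = 168 coefficients and reproduces
  every measurement with virtually zero error
  (`fit_parametric_spline()`, `export_coefficients()`, `knot_residuals()`).
* **Which dependencies dominate?** Plug-in Shannon entropy and mutual
  information in bits, MI(X, Y) = H(X) + H(Y) − H(X, Y), over discretized
  temperature and responses, assembled into a dependence graph with a
  bin-count sensitivity sweep (`dependency_graph()`, `mi_sensitivity()`).

It also derives CIELab chroma C\* = √(a\*² + b\*²) and hue angle
H\* = atan2(b\*, a\*) for extract colour (`chroma_hue()`), models the
two-fold broth dilution ladder used in MIC/MBC assays
(`dilution_series()`), and ships a seeded synthetic-data generator with a
known ground truth (Gaussian concentration peak × linear temperature gain,
shared-latent cross-response coupling) for validating the whole pipeline
(`synthetic_config()`, `generate_extraction()`, `recovery_suite()`).

Three experiment tables are packaged as plain-CSV fixtures: the 5 × 3
factorial yield table (`table1`), the composition/antioxidant/colour
profile of the optimal extract (`table2`), and antimicrobial
zone/MIC/MBC records for four bacterial strains (`table3`).

## Worked example

```r
library(marcex)

ds <- load_fixture("table1")
rep <- optimize_extraction(ds)
rep$consensus
#> # A tibble: 1 × 3
#>   temperature_C concentration_pct n_responses_maximal
#> 1            65                60                   4
rep$fold_changes[c("response", "fold_change")]
#>   response fold_change
#> 1 TPC             1.47
#> 2 TFC             1.59
#> 3 TC              1.63
#> 4 TAC             1.45
```

All four yields peak at 65 °C in 60 % v/v ethanol (TPC 11.02 mg GAE/g DW),
and raising temperature from 30 to 65 °C at that concentration multiplies
the yields by 1.45–1.63.

```r
pts <- order_points(ds, "TPC", "lexicographic")
crv <- fit_parametric_spline(pts, k = 3)
crv
#> <piecewise_curve> order k = 3, 15 knots, 14 intervals, 168 coefficients (3 directions x 14 x 4)
#> parameterization: index; boundary: natural; point ordering: lexicographic
knot_residuals(crv, pts)$max_relative
#> [1] 1.858114e-16
```

The fitted curve passes through all 15 experimental points to machine
precision — the "virtually zero modeling error" the interpolating spline
guarantees by construction.

```r
g <- dependency_graph(ds)
g$edges[g$edges$from != g$edges$to, ]
#>    from        to    mi_bits
#>  1 temperature TPC     0.278
#>  5 TPC         TFC     1.31
#>  7 TPC         TAC     0.844
#>  ...
chroma_hue(a_star = 9.72, b_star = 1.22)
#> $C_star   9.8
#> $H_star_deg   7.2
```

The response–response edges (e.g. TPC–TAC, TPC–TFC) carry more information
than any temperature–response edge at the default 3-bin discretization —
the yields co-vary with each other more strongly than temperature drives
any one of them — and `mi_sensitivity(ds, 2:5)` shows the ordering is
stable across 2–5 bins. The extract colour sits at hue 7.2°, in the first
trigonometric quadrant where red tones dominate.

A thin command-line wrapper with `optimize`, `chroma` and `simulate`
subcommands is installed at `system.file("cli", "marcex", package =
"marcex")`.

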