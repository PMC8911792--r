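test_that("discretization follows the documented bin conventions", {
  labs <- discretize(c(0, 1, 2, 3), discretization_spec("equal_width", 2))
  expect_equal(as.integer(labs), c(1L, 1L, 2L, 2L))
  expect_equal(attr(labs, "edges"), c(0, 1.5, 3))

  ds <- load_fixture("table1")
  tl <- discretize(ds$temperature_C, discretization_spec("distinct_levels"))
  expect_equal(sort(unique(as.integer(tl))), 1:3)
  expect_equal(as.vector(table(tl)), c(5L, 5L, 5L))

  expect_warning(const <- discretize(rep(2, 6), discretization_spec("equal_width", 3)),
                 "Constant")
  expect_equal(shannon_entropy(const), 0)

  # a value sitting numerically on an interior edge drops to the lower bin
  v <- c(0, 1, 2, 3, 1.5)
  labs2 <- discretize(v, discretization_spec("equal_width", 2))
  expect_equal(as.integer(labs2)[5], 1L)

  ef <- discretize(c(1, 2, 3, 4, 100, 200), discretization_spec("equal_frequency", 2))
  expect_equal(as.vector(table(ef)), c(3L, 3L))
})

test_that("plug-in entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(1:3, each = 5)), log2(3))
  expect_equal(shannon_entropy(c("a", "b")), 1)
  expect_equal(shannon_entropy(rep("a", 7)), 0)
  # bounds: 0 <= H <= log2(m)
  set.seed(4)
  for (i in 1:20) {
    labs <- sample(1:4, 30, replace = TRUE)
    h <- shannon_entropy(labs)
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(labs))) + 1e-12)
  }
})

test_that("mutual information matches exhaustive summation on exact joints", {
  # identity: MI(x, x) = H(x)
  x <- rep(1:3, times = c(2, 5, 8))
  expect_equal(mutual_information(x, x), shannon_entropy(x))

  # independent fair coins, exact 4-cell joint -> 0 bits
  lab <- labels_from_joint(matrix(0.25, 2, 2), 100)
  expect_equal(mutual_information(lab$x, lab$y), 0)

  # perfectly dependent diagonal joint -> 1 bit
  lab <- labels_from_joint(matrix(c(0.5, 0, 0, 0.5), 2, 2), 100)
  expect_equal(mutual_information(lab$x, lab$y), 1)

  # random rational joints up to 4 x 4 against the cell-sum oracle
  set.seed(9)
  for (i in 1:25) {
    r <- sample(2:4, 1)
    cc <- sample(2:4, 1)
    counts <- matrix(stats::rpois(r * cc, 3), r, cc)
    counts[1, 1] <- counts[1, 1] + 1 # non-empty
    P <- counts / sum(counts)
    lab <- labels_from_joint(P, sum(counts))
    expect_equal(mutual_information(lab$x, lab$y), mi_from_joint(P),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is symmetric, non-negative and bounded by the marginal entropies", {
  set.seed(21)
  for (i in 1:30) {
    x <- sample(1:3, 40, replace = TRUE)
    y <- sample(1:4, 40, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(x), shannon_entropy(y)) + 1e-12)
  }
})

test_that("the factorial fixture shows response-response coupling dominating temperature", {
  ds <- load_fixture("table1")
  g <- dependency_graph(ds)
  expect_setequal(g$nodes, c("temperature", "TPC", "TFC", "TC", "TAC"))
  # self-edges carry entropies; temperature has three equally filled levels
  expect_equal(graph_edge(g, "temperature", "temperature"), log2(3))

  temp_edges <- vapply(c("TPC", "TFC", "TC", "TAC"),
                       function(r) graph_edge(g, "temperature", r), numeric(1))
  expect_gt(graph_edge(g, "TPC", "TAC"), max(temp_edges))
  expect_gt(graph_edge(g, "TPC", "TFC"), max(temp_edges))

  # a duplicated response shares all its information with its twin
  twin <- tibble::as_tibble(ds)
  twin$COPY_mean <- twin$TPC_mean
  twin$COPY_sd <- twin$TPC_sd
  g2 <- dependency_graph(extraction_dataset(twin))
  expect_equal(graph_edge(g2, "TPC", "COPY"), graph_edge(g2, "TPC", "TPC"),
               tolerance = 1e-12)
})

test_that("independent responses fall below a permutation null", {
  set.seed(5)
  x <- rnorm(300)
  y <- rnorm(300) # independent of x
  spec <- discretization_spec("equal_width", 3)
  lx <- discretize(x, spec)
  ly <- discretize(y, spec)
  observed <- mutual_information(lx, ly)
  null <- vapply(seq_len(999), function(i) {
    mutual_information(lx, sample(ly))
  }, numeric(1))
  expect_lte(observed, stats::quantile(null, 0.95))
})

test_that("bin-count sensitivity reports the ordering per binning", {
  ds <- load_fixture("table1")
  sens <- mi_sensitivity(ds, 2:5)
  expect_setequal(unique(sens$n_bins), 2:5)
  per_bin <- unique(sens[c("n_bins", "ordering_holds")])
  expect_equal(nrow(per_bin), 4)
  expect_type(per_bin$ordering_holds, "logical")

  # constant response: all its edges are zero across binnings
  flat <- tibble::as_tibble(ds)
  flat$FLAT_mean <- 5
  flat$FLAT_sd <- 0
  suppressWarnings({
    sens2 <- mi_sensitivity(extraction_dataset(flat), 2:4)
  })
  flat_edges <- sens2[(sens2$from == "FLAT") != (sens2$to == "FLAT"), ]
  expect_true(all(flat_edges$mi_bits == 0))
})

test_that("graph exports are well-formed", {
  g <- dependency_graph(load_fixture("table1"))
  js <- jsonlite::fromJSON(graph_to_json(g))
  expect_setequal(js$nodes, g$nodes)
  expect_equal(nrow(js$edges), nrow(g$edges))
  expect_equal(js$discretization$response$n_bins, 3)
  dot <- graph_to_dot(g)
  expect_match(dot, "^graph dependency \\{")
  expect_match(dot, "temperature -- TPC")
})
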