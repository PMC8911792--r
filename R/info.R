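#' Discretization specification
#'
#' Describes how a continuous variable is turned into labels before entropy
#' or mutual-information estimation. `"equal_width"` splits `[min, max]`
#' into `n_bins` equal bins, left-closed/right-open with the last bin
#' closed; `"equal_frequency"` places bin edges at quantiles;
#' `"distinct_levels"` gives every unique value its own label (intended for
#' designed factors such as a 3-level extraction temperature).
#'
#' @param method `"equal_width"`, `"equal_frequency"` or
#'   `"distinct_levels"`.
#' @param n_bins Number of bins (>= 2) for the binned methods; ignored for
#'   `"distinct_levels"`.
#' @return A `discretization_spec` list.
#' @examples
#' discretization_spec("equal_width", 3)
#' @export
discretization_spec <- function(method = c("equal_width", "equal_frequency",
                                           "distinct_levels"),
                                n_bins = 3L) {
  method <- c(method)[[1]]
  method <- match.arg(method, c("equal_width", "equal_frequency", "distinct_levels"))
  if (method != "distinct_levels") {
    if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2 ||
        n_bins != as.integer(n_bins)) {
      abort("`n_bins` must be an integer >= 2 for binned methods.")
    }
  }
  structure(list(method = method, n_bins = as.integer(n_bins)),
            class = "discretization_spec")
}

#' Discretize a numeric vector into labels
#'
#' Bins are left-closed/right-open with the last bin closed so the maximum
#' is not orphaned. A value within 1e-12 of an interior bin edge is assigned
#' to the lower bin, making labels insensitive to representation noise in
#' edges computed as `min + width * i`.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param spec A [discretization_spec()].
#' @return Integer label vector with attributes `edges` (bin edges, or the
#'   sorted unique values for `"distinct_levels"`) and `method`.
#' @examples
#' discretize(c(0, 1, 2, 3), discretization_spec("equal_width", 2))
#' @export
discretize <- function(values, spec = discretization_spec()) {
  stopifnot(inherits(spec, "discretization_spec"))
  if (length(values) == 0L || !is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be a non-empty numeric vector of finite values.")
  }
  if (spec$method == "distinct_levels") {
    lev <- sort(unique(values))
    labels <- match(values, lev)
    attr(labels, "edges") <- lev
    attr(labels, "method") <- spec$method
    return(labels)
  }
  rng <- range(values)
  if (rng[[1]] == rng[[2]]) {
    warn("Constant vector: single-bin discretization (entropy 0).")
    labels <- rep(1L, length(values))
    attr(labels, "edges") <- c(rng[[1]], rng[[2]])
    attr(labels, "method") <- spec$method
    return(labels)
  }
  edges <- if (spec$method == "equal_width") {
    seq(rng[[1]], rng[[2]], length.out = spec$n_bins + 1L)
  } else {
    unique(stats::quantile(values, probs = seq(0, 1, length.out = spec$n_bins + 1L),
                           names = FALSE, type = 7))
  }
  labels <- findInterval(values, edges, rightmost.closed = TRUE)
  # edge-snap: values within 1e-12 of an interior edge go to the lower bin
  interior <- edges[-c(1L, length(edges))]
  for (e in interior) {
    near <- abs(values - e) <= 1e-12
    labels[near] <- pmax(1L, findInterval(e, edges, rightmost.closed = TRUE) - 1L)
  }
  labels <- pmin(pmax(labels, 1L), length(edges) - 1L)
  attr(labels, "edges") <- edges
  attr(labels, "method") <- spec$method
  labels
}

#' Plug-in Shannon entropy in bits
#'
#' Maximum-likelihood (plug-in) estimator from observed label frequencies,
#' base-2 logarithm, no bias correction. With `m` distinct labels,
#' `0 <= H <= log2(m)`.
#'
#' @param labels Non-empty vector of labels (any atomic type).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(1:3, each = 5)) # log2(3)
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0L) abort("`labels` must be non-empty.")
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two label vectors, in bits
#'
#' `MI(X, Y) = H(X) + H(Y) - H(X, Y)` with plug-in entropies. Symmetric and
#' non-negative (tiny negative rounding residue is clamped to 0).
#'
#' @param x,y Equal-length label vectors.
#' @return Mutual information in bits.
#' @examples
#' x <- rep(1:3, each = 5)
#' mutual_information(x, x) # equals shannon_entropy(x)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  mi <- shannon_entropy(x) + shannon_entropy(y) -
    shannon_entropy(paste(x, y, sep = "\r"))
  max(mi, 0) # plug-in MI is >= 0; clamp float residue

}

#' Pairwise dependence graph of factors and responses
#'
#' Discretizes extraction temperature and the response means across
#' conditions, then computes plug-in mutual information in bits for every
#' factor-response and response-response pair. Self-edges carry the
#' variable's own entropy `H(X)`. The graph is undirected (MI is symmetric).
#'
#' @param ds An [extraction_dataset()].
#' @param spec_factor Discretization for temperature; default
#'   `"distinct_levels"`, matching a designed 3-level factor.
#' @param spec_response Discretization for responses; default equal-width
#'   with 3 bins, mirroring the factor's 3 levels.
#' @return A `dependency_graph`: list with `nodes`, `edges` (tibble `from`,
#'   `to`, `mi_bits`, including self-edges), and the discretization specs.
#' @examples
#' dependency_graph(load_fixture("table1"))
#' @export
dependency_graph <- function(ds,
                             spec_factor = discretization_spec("distinct_levels"),
                             spec_response = discretization_spec("equal_width", 3)) {
  stopifnot(inherits(ds, "extraction_dataset"))
  resp <- extraction_responses(ds)
  vars <- c(
    list(temperature = discretize(ds$temperature_C, spec_factor)),
    lapply(setNames(resp, resp), function(r) {
      discretize(ds[[paste0(r, "_mean")]], spec_response)
    })
  )
  nodes <- names(vars)
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  edges <- dplyr::bind_rows(
    tibble::tibble(
      from = nodes, to = nodes,
      mi_bits = unname(vapply(vars, shannon_entropy, numeric(1)))
    ),
    dplyr::bind_rows(lapply(pairs, function(p) {
      tibble::tibble(
        from = p[[1]], to = p[[2]],
        mi_bits = mutual_information(vars[[p[[1]]]], vars[[p[[2]]]])
      )
    }))
  )
  structure(
    list(nodes = nodes, edges = edges,
         spec_factor = spec_factor, spec_response = spec_response),
    class = "dependency_graph"
  )
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat(sprintf("<dependency_graph> %d nodes, %d edges (bits)\n",
              length(x$nodes), nrow(x$edges)))
  print(x$edges, n = nrow(x$edges))
  invisible(x)
}

#' Look up one edge weight of a dependency graph
#'
#' @param graph A `dependency_graph`.
#' @param from,to Node names (order irrelevant; `from == to` returns the
#'   entropy self-edge).
#' @return Mutual information in bits.
#' @export
graph_edge <- function(graph, from, to) {
  stopifnot(inherits(graph, "dependency_graph"))
  e <- graph$edges
  hit <- (e$from == from & e$to == to) | (e$from == to & e$to == from)
  if (!any(hit)) abort(sprintf("No edge between `%s` and `%s`.", from, to))
  e$mi_bits[which(hit)[[1]]]
}

#' Sensitivity of MI edges to the number of response bins
#'
#' Recomputes the dependence graph over a range of equal-width bin counts
#' and reports, per binning, whether the response-response interdependence
#' MI(TPC, TAC) still exceeds the strongest temperature-response edge — the
#' qualitative ordering the analysis rests on, probed because the printed
#' bit values of the source experiment depend on an unstated binning.
#'
#' @param ds An [extraction_dataset()] whose responses include `TPC` and
#'   `TAC` (the ordering flag is `NA` otherwise).
#' @param n_bins_range Integer vector of bin counts (each >= 2).
#' @return Tibble: `n_bins`, `from`, `to`, `mi_bits`, plus per-binning
#'   attribute column `ordering_holds` repeated on each row.
#' @examples
#' mi_sensitivity(load_fixture("table1"), 2:5)
#' @export
mi_sensitivity <- function(ds, n_bins_range = 2:5) {
  stopifnot(inherits(ds, "extraction_dataset"))
  dplyr::bind_rows(lapply(n_bins_range, function(b) {
    g <- dependency_graph(
      ds, spec_response = discretization_spec("equal_width", b)
    )
    e <- g$edges
    resp <- setdiff(g$nodes, "temperature")
    holds <- NA
    if (all(c("TPC", "TAC") %in% resp)) {
      mi_resp <- graph_edge(g, "TPC", "TAC")
      mi_temp <- max(vapply(resp, function(r) graph_edge(g, "temperature", r),
                            numeric(1)))
      holds <- mi_resp > mi_temp
    }
    e$n_bins <- b
    e$ordering_holds <- holds
    e[c("n_bins", "from", "to", "mi_bits", "ordering_holds")]
  }))
}

#' Export a dependency graph
#'
#' `graph_to_json()` writes the edge list (with the discretization recorded)
#' as JSON; `graph_to_dot()` renders Graphviz DOT text with MI edge labels.
#'
#' @param graph A `dependency_graph`.
#' @param path Output file path for JSON; `NULL` returns the string.
#' @param digits Edge-label digits in DOT output.
#' @return JSON string (invisibly if written to `path`) or DOT text.
#' @export
graph_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "dependency_graph"))
  obj <- list(
    nodes = graph$nodes,
    discretization = list(
      factor = unclass(graph$spec_factor),
      response = unclass(graph$spec_response)
    ),
    edges = graph$edges
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname graph_to_json
#' @export
graph_to_dot <- function(graph, digits = 3) {
  stopifnot(inherits(graph, "dependency_graph"))
  e <- graph$edges[graph$edges$from != graph$edges$to, ]
  lines <- c(
    "graph dependency {",
    sprintf("  %s [shape=box];", graph$nodes),
    sprintf('  %s -- %s [label="%s"];', e$from, e$to,
            formatC(e$mi_bits, digits = digits, format = "f")),
    "}"
  )
  paste(lines, collapse = "\n")
}
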