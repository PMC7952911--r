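#' Pseudorandom delay code for one data set
#'
#' One integer delay offset per output connection, drawn uniformly from
#' `[0, code_range]` cycles, reproducible from the seed. Adding a set's code
#' to every delay line that originates in that set re-codes the delay space:
#' spikes from within one set share the offsets at each output and stay
#' coincident, while cross-set coincidences are dispersed whenever the two
#' codes disagree at an output.
#'
#' @param n_outputs number of output neurons.
#' @param code_range maximum offset in cycles (offsets are uniform integers
#'   on `[0, code_range]`).
#' @param seed RNG seed; identical (seed, connection) pairs always give the
#'   identical offset.
#' @return a `set_code`: list with integer `offsets` (length `n_outputs`),
#'   `code_range`, `seed`.
#' @export
set_code <- function(n_outputs, code_range = 4, seed = 1L) {
  if (code_range < 0) stop_symspike("code_range must be >= 0", "invalid_input")
  offsets <- with_seed(seed, sample.int(code_range + 1L, n_outputs, replace = TRUE) - 1L)
  structure(list(offsets = as.integer(offsets),
                 code_range = as.integer(code_range), seed = as.integer(seed)),
            class = "set_code")
}

# internal: return topology with per-set per-output offsets added to the
# delay lines originating at the given input neuron ids
apply_set_codes <- function(topology, ids_a, ids_b, code_a, code_b) {
  n <- nrow(topology$delays)
  if (length(code_a$offsets) != n || length(code_b$offsets) != n) {
    stop_symspike("code length must match the number of outputs", "invalid_input")
  }
  d <- topology$delays
  if (length(ids_a)) {
    d[ids_a, ] <- d[ids_a, , drop = FALSE] +
      matrix(code_a$offsets, length(ids_a), n, byrow = TRUE)
  }
  if (length(ids_b)) {
    d[ids_b, ] <- d[ids_b, , drop = FALSE] +
      matrix(code_b$offsets, length(ids_b), n, byrow = TRUE)
  }
  topology$delays <- d
  topology
}

# internal: shared validation for the set operations
check_disjoint_sets <- function(set_a, set_b) {
  a <- as_point_tbl(set_a)
  b <- as_point_tbl(set_b)
  if (nrow(a) == 0 && nrow(b) == 0) {
    stop_symspike("both point sets are empty", "empty_input")
  }
  key_a <- paste(a$x, a$y)
  key_b <- paste(b$x, b$y)
  if (length(intersect(key_a, key_b))) {
    stop_symspike("point sets overlap: set membership is ambiguous", "ambiguous_membership")
  }
  list(a = a, b = b)
}

#' Intra-set symmetry map
#'
#' Runs the combined input through the delay network with set A's code
#' applied to connections from A and set B's code to connections from B.
#' Within-set coincidences are preserved exactly (a common offset at an
#' output is a pure time shift); cross-set coincidences are dispersed with
#' probability `code_range / (code_range + 1)` per output.
#'
#' @param set_a,set_b disjoint point sets (data frames with `x`, `y`).
#' @param width,height grid size.
#' @param codes list of two [set_code()]s (for A and B); by default drawn
#'   with `code_range` and seeds `seed` and `seed + 1`.
#' @param params [lif_params()].
#' @param metric,k,base delay rule, see [build_symmetry_network()].
#' @param code_range,seed used to draw default codes.
#' @return a `symmetry_map` of the intra-set coincidences.
#' @export
intra_set_map <- function(set_a, set_b, width, height, codes = NULL,
                          params = lif_params(),
                          metric = c("manhattan", "euclidean"),
                          k = 1, base = 2, code_range = 4, seed = 1L) {
  metric <- arg_match(metric)
  sets <- check_disjoint_sets(set_a, set_b)
  topo <- build_symmetry_network(width, height, metric, k, base)
  n <- nrow(topo$delays)
  codes <- codes %||% list(set_code(n, code_range, seed),
                           set_code(n, code_range, seed + 1L))
  ids_a <- if (nrow(sets$a)) point_ids(sets$a, topo) else integer(0)
  ids_b <- if (nrow(sets$b)) point_ids(sets$b, topo) else integer(0)
  coded <- apply_set_codes(topo, ids_a, ids_b, codes[[1]], codes[[2]])
  trace <- run_symmetry(bind_rows(sets$a, sets$b), coded, params)
  map <- detect_symmetry(trace)
  attr(map, "source") <- "snn-intra-set"
  map
}

#' Inter-set symmetry map
#'
#' The uncoded combined-input map contains the union of intra- and
#' inter-set symmetry. Inhibitory connections from the intra-set network
#' subtract its result at matched output neurons (clamped at zero), leaving
#' only the between-set symmetry.
#'
#' @inheritParams intra_set_map
#' @return a `symmetry_map` of the inter-set coincidences; attributes
#'   `union_map` and `intra_map` carry the two operands.
#' @export
inter_set_map <- function(set_a, set_b, width, height, codes = NULL,
                          params = lif_params(),
                          metric = c("manhattan", "euclidean"),
                          k = 1, base = 2, code_range = 4, seed = 1L) {
  metric <- arg_match(metric)
  sets <- check_disjoint_sets(set_a, set_b)
  topo <- build_symmetry_network(width, height, metric, k, base)
  union_trace <- run_symmetry(bind_rows(sets$a, sets$b), topo, params)
  union_map <- detect_symmetry(union_trace)
  intra <- intra_set_map(sets$a, sets$b, width, height, codes, params,
                         metric, k, base, code_range, seed)
  out <- union_map
  out$value <- pmax(0, union_map$value - intra$value)
  attr(out, "source") <- "snn-inter-set"
  attr(out, "union_map") <- union_map
  attr(out, "intra_map") <- intra
  out
}
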