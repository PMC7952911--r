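#' Synchronization-layer parameters
#'
#' A layer of slow-leaking LIF neurons sitting above a symmetry network.
#' Lower-layer fires arrive asynchronously (coincidence times depend on the
#' data) and are stored: the sync threshold exceeds one stored pulse plus the
#' slow leak can erase it only over many cycles. When the periodic timing
#' pulse of amplitude `release_amplitude` arrives, every neuron holding a
#' stored spike crosses threshold and all stored spikes are released
#' simultaneously — re-synchronized input for the next symmetry layer.
#'
#' @param leak slow leak (units/cycle); must be below the symmetry layer's
#'   leak.
#' @param timing_period cycles between timing pulses; defaults to the lower
#'   network's latency + 2 and must not be below the latency.
#' @param release_amplitude amplitude of the timing pulse; alone it must not
#'   fire an empty sync neuron (`threshold > release_amplitude`).
#' @param threshold sync firing threshold.
#' @param store_amplitude amplitude of a stored lower-layer spike.
#' @return a `sync_layer_params` list.
#' @export
sync_layer_params <- function(leak = 0.01, timing_period = NULL,
                              release_amplitude = 1, threshold = 1.75,
                              store_amplitude = 1) {
  if (threshold <= release_amplitude) {
    stop_symspike("sync threshold must exceed the release pulse alone", "invalid_input")
  }
  if (leak < 0) stop_symspike("sync leak must be >= 0", "invalid_input")
  structure(list(leak = leak, timing_period = timing_period,
                 release_amplitude = release_amplitude,
                 threshold = threshold, store_amplitude = store_amplitude),
            class = "sync_layer_params")
}

# internal: run the sync layer over a lower-layer trace; returns the set of
# sync neurons (as points) that fire at the timing pulse, plus the release
# cycle. Cycle-by-cycle accumulator arithmetic, same update rule as `step`.
run_sync_layer <- function(trace, sync) {
  topo <- trace$topology
  lat <- latency(topo)
  period <- sync$timing_period %||% (lat + 2L)
  if (period < lat) {
    stop_symspike("timing period is below the lower-layer latency", "desynchronization_risk")
  }
  if (sync$leak >= trace$params$leak) {
    stop_symspike("sync layer must leak slower than the layer below", "invalid_input")
  }
  n <- nrow(topo$delays)
  acc <- numeric(n)
  horizon <- min(period, trace$cycles)
  for (t in seq_len(horizon)) {
    stored <- sync$store_amplitude * trace$fires[t, ]
    acc <- pmax(0, acc + stored - sync$leak)
    # no release yet: a stored spike alone stays below threshold
  }
  if (period > trace$cycles) {
    acc <- pmax(0, acc - sync$leak * (period - trace$cycles))
  }
  acc <- pmax(0, acc + sync$release_amplitude - sync$leak)
  fired <- acc >= sync$threshold
  out <- topo$neurons[fired, c("x", "y")]
  out$weight <- 1
  list(released = as_tibble(out), release_cycle = period)
}

#' Two-layer hierarchical symmetry detection
#'
#' Runs the delay-line symmetry network, stores its output fires in a
#' synchronization layer, releases them simultaneously on the timing pulse
#' into a second, identical symmetry network, and returns the top-layer
#' coincidence map: the symmetry of the symmetry points.
#'
#' @param points input pattern (data frame with `x`, `y`).
#' @param width,height grid size shared by all layers.
#' @param params [lif_params()] for both symmetry layers.
#' @param sync [sync_layer_params()].
#' @param metric,k,base delay rule, see [build_symmetry_network()].
#' @return the top-layer `symmetry_map`; attributes `lower_map` (first-layer
#'   coincidence map) and `released` (the re-synchronized point set).
#' @export
run_hierarchical <- function(points, width, height, params = lif_params(),
                             sync = sync_layer_params(),
                             metric = c("manhattan", "euclidean"),
                             k = 1, base = 2) {
  metric <- arg_match(metric)
  points <- as_point_tbl(points)
  topo <- build_symmetry_network(width, height, metric, k, base)
  if (nrow(points) == 0) {
    map <- new_symmetry_map(matrix(0, height, width), source = "snn-hierarchy")
    attr(map, "released") <- points
    return(map)
  }
  trace1 <- run_symmetry(points, topo, params)
  rel <- run_sync_layer(trace1, sync)
  if (nrow(rel$released) == 0) {
    map <- new_symmetry_map(matrix(0, height, width), source = "snn-hierarchy")
  } else {
    trace2 <- run_symmetry(rel$released, topo, params)
    map <- detect_symmetry(trace2)
    attr(map, "source") <- "snn-hierarchy"
  }
  attr(map, "lower_map") <- detect_symmetry(trace1)
  attr(map, "released") <- rel$released
  map
}

#' Recurrent symmetry detection
#'
#' Feeds the synchronized output fires back to the input layer: after each
#' presentation the fired outputs are unioned with the original input
#' pattern and the network is re-run. The dynamics resemble repeated
#' application of the density algorithm with feedback.
#'
#' @inheritParams run_hierarchical
#' @param cycles number of presentations k (>= 1); `k = 1` is the
#'   feed-forward result.
#' @return the k-th presentation's `symmetry_map`; attribute `input_points`
#'   holds the final augmented input.
#' @export
run_recurrent <- function(points, width, height, cycles = 1,
                          params = lif_params(), sync = sync_layer_params(),
                          metric = c("manhattan", "euclidean"),
                          k = 1, base = 2) {
  if (cycles < 1) stop_symspike("cycles must be >= 1", "invalid_input")
  metric <- arg_match(metric)
  original <- as_point_tbl(points, allow_empty = FALSE)
  topo <- build_symmetry_network(width, height, metric, k, base)
  current <- original
  trace <- run_symmetry(current, topo, params)
  for (i in seq_len(cycles - 1)) {
    rel <- run_sync_layer(trace, sync)
    current <- distinct(bind_rows(original, rel$released), .data$x, .data$y,
                        .keep_all = TRUE)
    trace <- run_symmetry(current, topo, params)
  }
  map <- detect_symmetry(trace)
  attr(map, "source") <- "snn-recurrent"
  attr(map, "input_points") <- current
  map
}
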