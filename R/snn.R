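#' LIF neuron parameters
#'
#' Discrete-time leaky-integrate-and-fire parameters used by the simulator.
#' Each cycle an output neuron adds the arriving pulse amplitudes to its
#' accumulator, subtracts the leak, clamps at zero, fires when the result
#' reaches the threshold, and (by default) resets to zero on firing. The
#' threshold must exceed a single pulse amplitude so a lone pulse can never
#' fire a coincidence detector; the defaults A = 1, theta = 1.5, leak = 0.5
#' give a strict one-cycle coincidence window for pulse pairs. An m-fold
#' detector uses `threshold = (m - 0.5) * pulse_amplitude`.
#'
#' @param threshold firing threshold theta (accumulator units).
#' @param leak lambda subtracted each cycle (units/cycle, >= 0).
#' @param pulse_amplitude amplitude A of one arriving pulse.
#' @param reset_on_fire reset the accumulator to zero after firing.
#' @return a `lif_params` list.
#' @export
lif_params <- function(threshold = 1.5, leak = 0.5, pulse_amplitude = 1,
                       reset_on_fire = TRUE) {
  if (threshold <= pulse_amplitude) {
    stop_symspike("threshold must exceed a single pulse amplitude", "invalid_input")
  }
  if (leak < 0) stop_symspike("leak must be >= 0", "invalid_input")
  structure(list(threshold = threshold, leak = leak,
                 pulse_amplitude = pulse_amplitude,
                 reset_on_fire = reset_on_fire),
            class = "lif_params")
}

#' Build a fully connected delay-line symmetry network
#'
#' Every input-grid neuron is connected to every output-grid neuron by a
#' delay line whose length in clock cycles is proportional to the distance
#' between their grid positions: `L(i, o) = round(k * d(i, o)) + base`
#' (half-away-from-zero rounding, same rule as distance binning). Input and
#' output grids coincide (`width` x `height` each), giving
#' `(width * height)^2` delay lines. With the Manhattan metric on an 8x8
#' grid, `k = 1`, `base = 2`, that is 4096 lines with maximum length
#' 14 + 2 = 16.
#'
#' Neuron ids are 1-based row-major: `id = y * width + x + 1`.
#'
#' @param width,height grid size (>= 1).
#' @param metric `"manhattan"` (the hardware-friendly default) or
#'   `"euclidean"`.
#' @param k propagation speed factor in cycles per pixel.
#' @param base pipeline offset added to every line (cycles, >= 1).
#' @return an `snn_topology`: list with the delay matrix (`delays[i, o]`),
#'   grid metadata and neuron coordinates.
#' @examples
#' topo <- build_symmetry_network(8, 8)
#' n_delay_lines(topo)   # 4096
#' max(topo$delays)      # 16
#' @export
build_symmetry_network <- function(width, height,
                                   metric = c("manhattan", "euclidean"),
                                   k = 1, base = 2) {
  metric <- arg_match(metric)
  if (width < 1 || height < 1) {
    stop_symspike("grid dimensions must be >= 1", "invalid_input")
  }
  if (base < 1) stop_symspike("base offset must be >= 1 cycle", "invalid_input")
  n <- width * height
  x <- rep(0:(width - 1), times = height)
  y <- rep(0:(height - 1), each = width)
  d <- distance_matrix(x, y, x, y, metric)
  delays <- matrix(as.integer(round_half_away(k * d)) + as.integer(base),
                   nrow = n, ncol = n)
  structure(
    list(width = width, height = height, metric = metric,
         k = k, base = as.integer(base), delays = delays,
         neurons = tibble(id = seq_len(n), x = as.integer(x), y = as.integer(y))),
    class = "snn_topology"
  )
}

#' @export
print.snn_topology <- function(x, ...) {
  cat(sprintf("<snn_topology %dx%d -> %dx%d (%s), %d delay lines, max length %d>\n",
              x$width, x$height, x$width, x$height, x$metric,
              n_delay_lines(x), max(x$delays)))
  invisible(x)
}

#' @rdname build_symmetry_network
#' @param topology an `snn_topology`.
#' @export
n_delay_lines <- function(topology) length(topology$delays)

#' Input-to-output latency of the network
#'
#' The longest delay line plus the accumulation pipeline: the number of clock
#' cycles from synchronized injection until the farthest pulse can have been
#' accumulated and thresholded. The 8x8 Manhattan network with `k = 1`,
#' `base = 2` and a two-stage accumulator has latency 16 + 2 = 18 cycles.
#'
#' @param topology an `snn_topology`.
#' @param accumulation_stages adder/threshold pipeline depth in cycles.
#' @return latency in clock cycles.
#' @export
latency <- function(topology, accumulation_stages = 2) {
  max(topology$delays) + accumulation_stages
}

#' Perturb delay lines with Gaussian noise
#'
#' Each line length is replaced by `max(base, round(L + N(0, sd)))`.
#' Deterministic given `seed`; `sd = 0` returns the topology unchanged.
#' Delay noise relaxes strict coincidence: approximate symmetries become
#' visible at the cost of noise on exact ones.
#'
#' @param topology an `snn_topology`.
#' @param sd noise standard deviation in cycles (>= 0).
#' @param seed RNG seed.
#' @return the perturbed `snn_topology`.
#' @export
add_delay_noise <- function(topology, sd, seed = 1L) {
  if (sd < 0) stop_symspike("sd must be >= 0", "invalid_input")
  if (sd == 0) return(topology)
  noise <- with_seed(seed, rnorm(length(topology$delays), 0, sd))
  delays <- round_half_away(topology$delays + noise)
  topology$delays <- matrix(pmax(as.integer(topology$base), as.integer(delays)),
                            nrow = nrow(topology$delays))
  topology
}

#' Initialize simulator state
#'
#' The delay lines can be represented as shift registers (a bit per cycle of
#' travel, shifted every clock) or as countdown registers (a pending count
#' per in-flight pulse). The two representations are observationally
#' equivalent; countdown is the default because its cost scales with the
#' number of in-flight pulses rather than total line length.
#'
#' @param topology an `snn_topology`.
#' @param params a [lif_params()].
#' @param representation `"countdown"` or `"shift_register"`.
#' @return an `snn_state`.
#' @export
new_sim_state <- function(topology, params = lif_params(),
                          representation = c("countdown", "shift_register")) {
  representation <- arg_match(representation)
  n <- nrow(topology$delays)
  st <- list(topology = topology, params = params,
             representation = representation,
             cycle = 0L, acc = numeric(n),
             arrivals = integer(n), fires = logical(n))
  if (representation == "countdown") {
    st$pending_out <- integer(0)
    st$pending_left <- integer(0)
  } else {
    st$occupancy <- matrix(0L, nrow = length(topology$delays),
                           ncol = max(topology$delays))
  }
  structure(st, class = "snn_state")
}

#' Advance the network one clock cycle
#'
#' Order of operations within a cycle: (1) inject new spikes into the delay
#' lines, (2) advance every line one cycle and collect emerging pulses,
#' (3) sum arrivals into the accumulators, (4) subtract the leak, (5) clamp
#' at zero, (6) compare to threshold and emit fires, (7) reset fired
#' accumulators. A pulse injected at cycle t on a line of length L arrives at
#' cycle t + L under either representation.
#'
#' @param state an `snn_state` from [new_sim_state()].
#' @param inject integer ids of input neurons spiking this cycle (each emits
#'   one pulse into every one of its delay lines), or a point-set data frame.
#' @return the updated `snn_state`; fields `arrivals`, `acc`, `fires` hold
#'   this cycle's per-output values.
#' @export
step <- function(state, inject = integer(0)) {
  topo <- state$topology
  n <- nrow(topo$delays)
  if (is.data.frame(inject)) inject <- point_ids(inject, topo)
  inject <- as.integer(inject)

  if (state$representation == "countdown") {
    if (length(inject)) {
      state$pending_out <- c(state$pending_out, rep(seq_len(n), each = length(inject)))
      state$pending_left <- c(state$pending_left,
                              as.vector(topo$delays[inject, , drop = FALSE]))
    }
    state$pending_left <- state$pending_left - 1L
    due <- state$pending_left == 0L
    arrivals <- tabulate(state$pending_out[due], nbins = n)
    keep <- !due
    state$pending_out <- state$pending_out[keep]
    state$pending_left <- state$pending_left[keep]
  } else {
    occ <- state$occupancy
    if (length(inject)) {
      line <- rep((inject - 1L) * n, each = n) + rep(seq_len(n), times = length(inject))
      len <- as.vector(t(topo$delays[inject, , drop = FALSE]))
      idx <- cbind(line, len)
      occ[idx] <- occ[idx] + 1L
    }
    emerging <- occ[, 1]
    occ <- cbind(occ[, -1, drop = FALSE], 0L)
    state$occupancy <- occ
    # line id l = (i - 1) * n + o delivers to output o
    out_of_line <- rep(seq_len(n), times = n)
    arrivals <- as.integer(rowsum(emerging, out_of_line))
  }

  p <- state$params
  acc <- pmax(0, state$acc + p$pulse_amplitude * arrivals - p$leak)
  fires <- acc >= p$threshold
  if (p$reset_on_fire) acc[fires] <- 0
  state$acc <- acc
  state$arrivals <- as.integer(arrivals)
  state$fires <- fires
  state$cycle <- state$cycle + 1L
  state
}

# internal: map 0-based grid points to 1-based neuron ids
point_ids <- function(points, topology) {
  points <- as_point_tbl(points)
  bad <- points$x < 0 | points$x >= topology$width |
    points$y < 0 | points$y >= topology$height
  if (any(bad)) stop_symspike("points fall outside the grid", "invalid_input")
  as.integer(points$y) * topology$width + as.integer(points$x) + 1L
}

#' Run the symmetry network on an input pattern
#'
#' All active input neurons fire exactly once, simultaneously at cycle 0
#' (one pulse per cycle per line). The cycle-accurate simulation records, per
#' cycle and output neuron, the number of pulses arriving, the accumulator
#' value and the fires. Because delays are proportional to distance, pulses
#' from points equidistant to an output arrive coincidently there: the
#' per-cycle arrival maxima reproduce the distance-histogram peaks.
#'
#' @param points input pattern: data frame with `x`, `y` (0-based grid
#'   coordinates).
#' @param topology an `snn_topology`.
#' @param params a [lif_params()].
#' @param cycles simulation horizon; must be at least [latency()] (default
#'   latency + 2 to close the coincidence window).
#' @param representation delay-line representation, see [new_sim_state()].
#' @return an `snn_trace`: list with `arrivals`, `acc`, `fires` (cycle x
#'   neuron matrices), the topology, parameters and input.
#' @export
run_symmetry <- function(points, topology, params = lif_params(),
                         cycles = NULL,
                         representation = c("countdown", "shift_register")) {
  representation <- arg_match(representation)
  points <- as_point_tbl(points)
  cycles <- cycles %||% (latency(topology) + 2L)
  if (cycles < latency(topology)) {
    stop_symspike("simulation horizon is below the network latency", "insufficient_horizon")
  }
  n <- nrow(topology$delays)
  st <- new_sim_state(topology, params, representation)
  arrivals <- matrix(0L, nrow = cycles, ncol = n)
  acc <- matrix(0, nrow = cycles, ncol = n)
  fires <- matrix(FALSE, nrow = cycles, ncol = n)
  for (t in seq_len(cycles)) {
    st <- step(st, if (t == 1L) points else integer(0))
    arrivals[t, ] <- st$arrivals
    acc[t, ] <- st$acc
    fires[t, ] <- st$fires
  }
  structure(
    list(topology = topology, params = params, input = points,
         cycles = cycles, representation = representation,
         arrivals = arrivals, acc = acc, fires = fires),
    class = "snn_trace"
  )
}

#' @export
print.snn_trace <- function(x, ...) {
  cat(sprintf("<snn_trace %d cycles, %d inputs, %d output fires>\n",
              x$cycles, nrow(x$input), sum(x$fires)))
  invisible(x)
}

#' Coincidence map of a simulation trace
#'
#' The symmetry density read out of the spiking network: for every output
#' neuron, the greatest number of pulses that arrived in a single cycle.
#' With `k = 1` this equals [symmetry_density()] of the same input computed
#' with whole-cycle bins (`decimals = 0`), bin for bin.
#'
#' @param trace an `snn_trace` from [run_symmetry()].
#' @return a `symmetry_map` over the output grid.
#' @export
detect_symmetry <- function(trace) {
  topo <- trace$topology
  peak <- apply(trace$arrivals, 2, max)
  vals <- matrix(peak, nrow = topo$height, ncol = topo$width, byrow = TRUE)
  new_symmetry_map(vals, config = list(metric = topo$metric, k = topo$k,
                                       base = topo$base),
                   source = "snn")
}

#' Output neurons that fired during a trace
#'
#' @param trace an `snn_trace`.
#' @return tibble of grid coordinates (`x`, `y`, `weight = 1`) of output
#'   neurons with at least one fire.
#' @export
fired_points <- function(trace) {
  ids <- which(apply(trace$fires, 2, any))
  out <- trace$topology$neurons[ids, c("x", "y")]
  out$weight <- 1
  as_tibble(out)
}
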