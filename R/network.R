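#' Random directed connectivity
#'
#' Erdos-Renyi directed topology: every ordered pair of distinct neurons is
#' connected independently with probability `p_connect`. Self-connections
#' are excluded.
#'
#' @param N Number of neurons (>= 2).
#' @param p_connect Connection probability in `[0, 1]`.
#' @return A tibble of directed edges with columns `from`, `to` (1-based).
#' @export
build_topology <- function(N, p_connect = 0.3) {
  stopifnot(N >= 2, p_connect >= 0, p_connect <= 1)
  pairs <- expand.grid(from = seq_len(N), to = seq_len(N))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p_connect
  tibble::as_tibble(pairs[keep, , drop = FALSE])
}

#' Place neurons on a square grid
#'
#' Deterministically places `N` neurons on the first `N` sites of a
#' ceiling(sqrt(N)) x ceiling(sqrt(N)) lattice (row-major, x fastest).
#'
#' @param N Number of neurons (>= 1).
#' @param pitch Lattice spacing (um).
#' @return A tibble with columns `neuron`, `x`, `y` (um).
#' @export
place_on_grid <- function(N, pitch = 100) {
  stopifnot(N >= 1, pitch > 0)
  side <- ceiling(sqrt(N))
  i <- seq_len(N) - 1L
  tibble::tibble(
    neuron = seq_len(N),
    x = (i %% side) * pitch,
    y = (i %/% side) * pitch
  )
}

#' Distance-dependent conduction delays
#'
#' Per directed edge, delay = euclidean distance / velocity, rounded up to a
#' whole number of integration steps with a minimum of one step.
#'
#' @param positions Tibble from [place_on_grid()].
#' @param adjacency Edge tibble from [build_topology()].
#' @param velocity Conduction velocity (um/ms); must be > 0.
#' @param dt Integration step (ms) used for rounding.
#' @return `adjacency` with columns `delay` (ms) and `delay_steps` appended.
#' @export
compute_delays <- function(positions, adjacency, velocity = 200, dt = 0.1) {
  if (velocity <= 0) stop("velocity must be > 0", call. = FALSE)
  stopifnot(dt > 0)
  d <- sqrt((positions$x[adjacency$from] - positions$x[adjacency$to])^2 +
              (positions$y[adjacency$from] - positions$y[adjacency$to])^2)
  steps <- pmax(1L, as.integer(ceiling(d / velocity / dt - 1e-9)))
  dplyr::mutate(tibble::as_tibble(adjacency),
                delay = steps * dt, delay_steps = steps)
}

#' Virtual-electrode layout and pickup weights
#'
#' Twelve electrodes in a 4 x 3 grid with 300 um spacing (the single-well
#' layout of a 24-well MEA plate), centered on the neuron sheet. Each
#' electrode picks up a weighted sum of nearby membrane potentials with
#' exponentially decaying weight exp(-d / lambda), truncated to zero beyond
#' `cutoff`.
#'
#' @param positions Neuron positions from [place_on_grid()].
#' @param spacing Electrode spacing (um).
#' @param lambda Pickup decay length (um).
#' @param cutoff Pickup radius (um); weights are zero beyond it.
#' @return A list with `electrode_positions` (tibble: electrode, x, y) and
#'   `weights` (12 x N matrix, electrodes in rows).
#' @export
electrode_layout <- function(positions, spacing = 300, lambda = 30,
                             cutoff = 300) {
  ex <- rep(0:3, times = 3) * spacing
  ey <- rep(0:2, each = 4) * spacing
  # center electrode grid on the neuron sheet
  ex <- ex - mean(range(ex)) + mean(range(positions$x))
  ey <- ey - mean(range(ey)) + mean(range(positions$y))
  w <- matrix(0, nrow = 12, ncol = nrow(positions))
  for (e in 1:12) {
    d <- sqrt((positions$x - ex[e])^2 + (positions$y - ey[e])^2)
    w[e, ] <- ifelse(d <= cutoff, exp(-d / lambda), 0)
  }
  list(
    electrode_positions = tibble::tibble(electrode = 1:12, x = ex, y = ey),
    weights = w
  )
}

#' Virtual-electrode signals from membrane-potential traces
#'
#' Each electrode signal is the fixed weighted sum of the membrane
#' potentials of nearby neurons, mimicking extracellular MEA pickup.
#'
#' @param Vm_traces Neuron x time matrix of membrane potentials (mV).
#' @param electrode_weights Electrode x neuron weight matrix.
#' @return Electrode x time signal matrix.
#' @export
electrode_signal <- function(Vm_traces, electrode_weights) {
  if (ncol(electrode_weights) != nrow(Vm_traces)) {
    stop("electrode_weights columns must match Vm_traces rows",
         call. = FALSE)
  }
  electrode_weights %*% Vm_traces
}

#' Build a complete network layout
#'
#' Convenience constructor combining topology, grid placement, conduction
#' delays, synaptic weights and the virtual-electrode layout. Uses the
#' current R random-number state; seed management is done by the caller
#' (see [run_simulation()]).
#'
#' @param N Number of neurons.
#' @param p_connect Connection probability.
#' @param pitch Grid pitch (um).
#' @param velocity Conduction velocity (um/ms).
#' @param dt Integration step (ms), for delay rounding.
#' @param lambda,cutoff Electrode pickup parameters (um).
#' @return A list of class `network_layout` with `N`, `positions`, `edges`
#'   (from, to, weight, delay, delay_steps), `electrode_positions`,
#'   `electrode_weights`, and `bias` (pA per neuron).
#' @export
build_network <- function(N = 100, p_connect = 0.3, pitch = 100,
                          velocity = 200, dt = 0.1, lambda = 30,
                          cutoff = 300) {
  positions <- place_on_grid(N, pitch)
  edges <- build_topology(N, p_connect)
  if (nrow(edges) > 0) {
    edges <- compute_delays(positions, edges, velocity, dt)
    edges <- draw_weights(edges)
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            delay = numeric(), delay_steps = integer(),
                            weight = numeric())
  }
  el <- electrode_layout(positions, lambda = lambda, cutoff = cutoff)
  structure(
    list(N = N, positions = positions, edges = edges,
         electrode_positions = el$electrode_positions,
         electrode_weights = el$weights,
         bias = draw_bias_currents(N)),
    class = "network_layout"
  )
}
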