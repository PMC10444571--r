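#' Fraction of NMDA channels unblocked by magnesium
#'
#' Voltage-dependent relief of the magnesium block of the NMDA receptor,
#' u(Vm) = 1 / (1 + exp(-a * Vm) * Mg / b), evaluated instantaneously at the
#' postsynaptic potential. Strictly increasing in Vm; equals 1 at any
#' voltage when the magnesium concentration is zero.
#'
#' @param Vm Postsynaptic membrane potential (mV); vectorized.
#' @param params A [synapse_params()].
#' @return Unblocked fraction in `(0, 1]`.
#' @export
#' @examples
#' mg_unblock(0, synapse_params())   # ~0.7812 at 1 mM Mg
mg_unblock <- function(Vm, params = synapse_params()) {
  stopifnot(all(is.finite(Vm)))
  1 / (1 + exp(-params$a_mg * Vm) * params$mg_conc / params$b_mg)
}

#' One step of the synaptic gating variables
#'
#' Per presynaptic source: the AMPA open fraction `s_ampa` and the NMDA
#' auxiliary variable `x_nmda` jump by the arrival amount on each (delayed)
#' presynaptic spike arrival and decay exponentially with `tauAMPA` and
#' `tauNMDA_rise`; the NMDA open fraction `s_nmda` follows the saturating
#' kinetics ds/dt = -s/tauNMDA_decay + alphaNMDA * x * (1 - s) (forward
#' Euler). The AMPA rise time is neglected.
#'
#' @param state List with numeric vectors `s_ampa`, `s_nmda`, `x_nmda`
#'   (one element per presynaptic source).
#' @param arrivals Numeric or logical vector of spike-arrival amounts per
#'   source for this step (0/FALSE = none; short-term depression scales the
#'   amount at transmission time).
#' @param dt Step size (ms).
#' @param params A [synapse_params()].
#' @return Updated state list.
#' @export
gating_step <- function(state, arrivals, dt, params = synapse_params()) {
  stopifnot(dt > 0)
  a <- as.numeric(arrivals)
  s_ampa <- (state$s_ampa + a) * exp(-dt / params$tauAMPA)
  x_nmda <- (state$x_nmda + a) * exp(-dt / params$tauNMDA_rise)
  s <- state$s_nmda
  s <- s + dt * (-s / params$tauNMDA_decay +
                   params$alphaNMDA * x_nmda * (1 - s))
  s <- pmin(pmax(s, 0), 1)
  list(s_ampa = s_ampa, s_nmda = s, x_nmda = x_nmda)
}

#' One step of the short-term depression resource
#'
#' The available synaptic resource fraction recovers towards 1 with time
#' constant `tauD` and is decremented by `U * x` at each presynaptic spike
#' (applied after the recovery update; transmission uses the value before
#' the decrement).
#'
#' @param x_std Available resource fraction in `(0, 1]`; vectorized.
#' @param presyn_spiked Logical; did the presynaptic neuron spike this step?
#' @param dt Step size (ms).
#' @param params A [synapse_params()].
#' @return Updated resource fraction.
#' @export
#' @examples
#' std_step(1, TRUE, 0.1, synapse_params())  # 1 - U = 0.985
std_step <- function(x_std, presyn_spiked, dt, params = synapse_params()) {
  stopifnot(all(x_std > 0), all(x_std <= 1), dt > 0)
  x <- 1 + (x_std - 1) * exp(-dt / params$tauD)
  ifelse(presyn_spiked, x - params$U * x, x)
}

#' Draw synaptic weights for a set of edges
#'
#' Independent normal(mean 1, sd 0.7) weights per directed edge, clipped to
#' `[0, 2]`. Roughly 7.7% of raw draws fall below zero and are stored as
#' exactly 0 (silent synapses).
#'
#' @param edges A data frame of directed edges with columns `from`, `to`.
#' @param mean,sd,lower,upper Weight distribution and clipping bounds.
#' @return The `edges` tibble with a `weight` column appended.
#' @export
draw_weights <- function(edges, mean = 1, sd = 0.7, lower = 0, upper = 2) {
  stopifnot(nrow(edges) > 0)
  dplyr::mutate(
    tibble::as_tibble(edges),
    weight = pmin(pmax(stats::rnorm(dplyr::n(), mean, sd), lower), upper)
  )
}

#' Total synaptic current onto one postsynaptic neuron
#'
#' Sums the AMPA and NMDA conductances over presynaptic sources (weight
#' times open fraction, all weights multiplied by the global scaling factor
#' `S`), applies the magnesium unblock to the NMDA component, and converts
#' to current with reversal potentials at 0 mV, so the current depolarizes
#' at subthreshold potentials.
#'
#' @param Vm_post Postsynaptic potential (mV).
#' @param state Gating state list as in [gating_step()].
#' @param weights Numeric vector of synaptic weights, one per source.
#' @param params A [synapse_params()].
#' @return A one-row tibble with `I_ampa`, `I_nmda`, `I_total` (pA,
#'   positive = depolarizing).
#' @export
synaptic_current <- function(Vm_post, state, weights,
                             params = synapse_params()) {
  stopifnot(length(weights) == length(state$s_ampa),
            length(weights) == length(state$s_nmda))
  w <- weights * params$S
  I_ampa <- params$gAMPA_max * sum(w * state$s_ampa) *
    (params$EAMPA - Vm_post)
  I_nmda <- params$gNMDA_max * mg_unblock(Vm_post, params) *
    sum(w * state$s_nmda) * (params$ENMDA - Vm_post)
  tibble::tibble(I_ampa = I_ampa, I_nmda = I_nmda,
                 I_total = I_ampa + I_nmda)
}
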