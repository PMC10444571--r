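#' Single-neuron parameter set
#'
#' Constants of the conductance-based (Hodgkin-Huxley type) neuron model used
#' throughout the simulator. Defaults are the calibrated control values for
#' hiPSC-derived excitatory neurons: depolarized leak reversal and spike
#' threshold relative to classical cortical models, a slow spike-triggered
#' afterhyperpolarization (sAHP) conductance, and membrane noise.
#'
#' Ionic conductances and capacitance are membrane-area densities
#' (mS cm^-2, uF cm^-2); the sAHP conductance increment `alphaCa` (nS) and
#' bias currents (pA) are absolute quantities and are divided by `area`
#' before they enter the current-balance equation.
#'
#' @param Cm Membrane capacitance (uF cm^-2).
#' @param gK_max Maximal delayed-rectifier potassium conductance (mS cm^-2).
#' @param gNa_max Maximal voltage-gated sodium conductance (mS cm^-2).
#' @param gl Leak conductance (mS cm^-2).
#' @param EK,ENa,El Nernst potentials (mV); must satisfy EK < El < ENa.
#' @param VT Spike-threshold adjustment potential (mV); shifts the voltage
#'   dependence of all gating rate constants.
#' @param alphaCa sAHP conductance increment per emitted spike (nS).
#' @param tauAHP sAHP recovery time constant (s).
#' @param sigma Stationary standard deviation of the membrane-noise process
#'   on a passive membrane (mV).
#' @param area Membrane area used to reconcile absolute (nS, pA) and
#'   per-area (mS cm^-2) quantities (cm^2). The default 2.5e-6 cm^2 is a
#'   calibration choice: it sets the input resistance (~1.3 GOhm) and
#'   rheobase (~10-15 pA, the scale probed by the experimental current-step
#'   protocol) so that the +/-9.5 pA bias spread, the pA-scale synaptic
#'   currents and the sAHP conductance move the membrane by
#'   physiologically meaningful amounts, and the default network
#'   self-organizes into regular synchronous bursts.
#'
#' @return A list of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$alphaCa
neuron_params <- function(Cm = 1, gK_max = 5, gNa_max = 50, gl = 0.3,
                          EK = -80, ENa = 70, El = -39.2, VT = -30.4,
                          alphaCa = 0.0035, tauAHP = 6, sigma = 4.1,
                          area = 2.5e-6) {
  p <- list(Cm = Cm, gK_max = gK_max, gNa_max = gNa_max, gl = gl,
            EK = EK, ENa = ENa, El = El, VT = VT,
            alphaCa = alphaCa, tauAHP = tauAHP, sigma = sigma, area = area)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  stopifnot(
    p$Cm > 0, p$gK_max >= 0, p$gNa_max >= 0, p$gl >= 0,
    p$tauAHP > 0, p$sigma >= 0, p$area > 0, p$alphaCa >= 0,
    is.finite(p$VT)
  )
  if (!(p$EK < p$El && p$El < p$ENa)) {
    stop("Nernst potentials must satisfy EK < El < ENa", call. = FALSE)
  }
  invisible(p)
}

#' Synapse parameter set
#'
#' Constants of the AMPA/NMDA conductance synapse model with voltage-dependent
#' magnesium block of the NMDA receptor and short-term depression (STD) of the
#' presynaptic resource, following the Tsodyks-Markram formulation.
#'
#' @param gAMPA_max,gNMDA_max Maximal synaptic conductances (nS).
#' @param EAMPA,ENMDA Synaptic reversal potentials (mV).
#' @param alphaNMDA NMDA channel opening rate constant (kHz).
#' @param tauAMPA AMPA decay time constant (ms); the AMPA rise time is
#'   neglected.
#' @param tauNMDA_rise,tauNMDA_decay NMDA rise/decay time constants (ms).
#' @param mg_conc Extracellular magnesium concentration (mM).
#' @param a_mg Voltage sensitivity of the magnesium block (mV^-1).
#' @param b_mg Magnesium sensitivity of the block (mM).
#' @param tauD STD resource recovery time constant (ms).
#' @param U STD utilization fraction per presynaptic spike (dimensionless,
#'   in `[0, 1]`).
#' @param S Global synaptic scaling factor applied to all weights.
#'
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(gAMPA_max = 0.2808, gNMDA_max = 0.0981,
                           EAMPA = 0, ENMDA = 0, alphaNMDA = 0.5,
                           tauAMPA = 2, tauNMDA_rise = 2, tauNMDA_decay = 100,
                           mg_conc = 1, a_mg = 0.062, b_mg = 3.57,
                           tauD = 813, U = 0.015, S = 1) {
  p <- list(gAMPA_max = gAMPA_max, gNMDA_max = gNMDA_max,
            EAMPA = EAMPA, ENMDA = ENMDA, alphaNMDA = alphaNMDA,
            tauAMPA = tauAMPA, tauNMDA_rise = tauNMDA_rise,
            tauNMDA_decay = tauNMDA_decay,
            mg_conc = mg_conc, a_mg = a_mg, b_mg = b_mg,
            tauD = tauD, U = U, S = S)
  validate_synapse_params(p)
  structure(p, class = "synapse_params")
}

validate_synapse_params <- function(p) {
  stopifnot(
    p$gAMPA_max >= 0, p$gNMDA_max >= 0,
    p$tauAMPA > 0, p$tauNMDA_rise > 0, p$tauNMDA_decay > 0, p$tauD > 0,
    p$U >= 0, p$U <= 1, p$S >= 0, p$mg_conc >= 0, p$alphaNMDA >= 0
  )
  invisible(p)
}

#' Sodium-gate kinetics modifier
#'
#' A description of alterations to the voltage-gated sodium channel that a
#' channelopathy (e.g. an SCN1A mutation) could produce: multiplicative
#' scaling of the activation (m) and inactivation (h) rate constants,
#' voltage shifts of their activation curves, and scaling of the maximal
#' sodium conductance. The identity modifier leaves the channel unchanged.
#'
#' @param scale_alpha_m,scale_beta_m Multiplicative factors on the activation
#'   gate rate constants (> 0).
#' @param scale_alpha_h,scale_beta_h Multiplicative factors on the
#'   inactivation gate rate constants (> 0).
#' @param shift_activation,shift_inactivation Voltage shifts (mV) applied to
#'   the activation/inactivation rate curves; positive values shift the
#'   curves to more depolarized potentials.
#' @param scale_gNa Factor on the maximal sodium conductance (>= 0; 0 is a
#'   complete block, equivalent to tetrodotoxin).
#'
#' @return A list of class `rate_modifier`.
#' @export
#' @examples
#' rate_modifier()                      # identity
#' rate_modifier(scale_gNa = 0)         # full sodium block
#' rate_modifier(scale_alpha_m = 0.7, scale_beta_m = 0.7)
rate_modifier <- function(scale_alpha_m = 1, scale_beta_m = 1,
                          scale_alpha_h = 1, scale_beta_h = 1,
                          shift_activation = 0, shift_inactivation = 0,
                          scale_gNa = 1) {
  m <- list(scale_alpha_m = scale_alpha_m, scale_beta_m = scale_beta_m,
            scale_alpha_h = scale_alpha_h, scale_beta_h = scale_beta_h,
            shift_activation = shift_activation,
            shift_inactivation = shift_inactivation,
            scale_gNa = scale_gNa)
  stopifnot(
    m$scale_alpha_m > 0, m$scale_beta_m > 0,
    m$scale_alpha_h > 0, m$scale_beta_h > 0,
    is.finite(m$shift_activation), is.finite(m$shift_inactivation),
    m$scale_gNa >= 0
  )
  structure(m, class = "rate_modifier")
}

is_identity_modifier <- function(mod) {
  isTRUE(all.equal(unclass(mod), unclass(rate_modifier())))
}
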