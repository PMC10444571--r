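#' Gating rate constants of the sodium and potassium channels
#'
#' Voltage-dependent opening/closing rates of the activation (m) and
#' inactivation (h) gates of the sodium channel and the activation (n) gate
#' of the delayed-rectifier potassium channel, in the Traub-Miles form with
#' a threshold-adjustment potential `VT`. The removable singularities of
#' `alpha_m`, `beta_m` and `alpha_n` (where the denominator crosses zero)
#' are evaluated by their analytic limits.
#'
#' @param Vm Membrane potential (mV); vectorized.
#' @param VT Threshold-adjustment potential (mV).
#' @param mod A [rate_modifier()]; applied to the sodium-gate rates only.
#'
#' @return A tibble with columns `alpha_m`, `beta_m`, `alpha_h`, `beta_h`,
#'   `alpha_n`, `beta_n` (all in kHz = 1/ms), one row per element of `Vm`.
#' @export
#' @examples
#' rate_constants(-30.4 + 13, -30.4)$alpha_m  # analytic limit: 1.28 kHz
rate_constants <- function(Vm, VT, mod = rate_modifier()) {
  if (any(!is.finite(Vm)) || !is.finite(VT)) {
    stop("Vm and VT must be finite", call. = FALSE)
  }
  va <- Vm - mod$shift_activation    # activation-gate voltage
  vi <- Vm - mod$shift_inactivation  # inactivation-gate voltage

  tibble::tibble(
    alpha_m = mod$scale_alpha_m * 0.32 * .sing_ratio(-(va - VT - 13), 4),
    beta_m  = mod$scale_beta_m  * 0.28 * .sing_ratio(va - VT - 40, 5),
    alpha_h = mod$scale_alpha_h * 0.128 * exp(-(vi - VT - 17) / 18),
    beta_h  = mod$scale_beta_h  * 4 / (1 + exp(-(vi - VT - 40) / 5)),
    alpha_n = 0.032 * .sing_ratio(-(Vm - VT - 15), 5),
    beta_n  = 0.5 * exp(-(Vm - VT - 10) / 40)
  )
}

# x / (exp(x/s) - 1), with the analytic limit s at the removable
# singularity x -> 0 (tolerance 1e-9 mV).
.sing_ratio <- function(x, s) {
  out <- numeric(length(x))
  sing <- abs(x) < 1e-9
  out[sing] <- s
  out[!sing] <- x[!sing] / (exp(x[!sing] / s) - 1)
  out
}

#' Steady-state gate values at a fixed potential
#'
#' @inheritParams rate_constants
#' @return A tibble with columns `m`, `h`, `n` in `[0, 1]`.
#' @export
gate_steady_state <- function(Vm, VT, mod = rate_modifier()) {
  r <- rate_constants(Vm, VT, mod)
  tibble::tibble(
    m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n)
  )
}

#' Deterministic membrane drift
#'
#' The deterministic part of dVm/dt for one neuron: ionic currents
#' (potassium, sodium, leak), the absolute currents (bias, synaptic input,
#' spike-triggered sAHP) converted to per-area densities via `params$area`.
#' The sAHP term hyperpolarizes whenever Vm > EK. Membrane noise is added
#' separately by the integration engine.
#'
#' @param state A list with `Vm` (mV), `m`, `h`, `n` (gates in `[0, 1]`),
#'   `gAHP` (nS) and `I_bias` (pA).
#' @param params A [neuron_params()].
#' @param I_syn Synaptic current (pA, positive = depolarizing).
#' @param mod A [rate_modifier()]; only `scale_gNa` affects the drift.
#'
#' @return dVm/dt in mV/ms.
#' @export
membrane_derivative <- function(state, params, I_syn = 0,
                                mod = rate_modifier()) {
  stopifnot(state$m >= 0, state$m <= 1, state$h >= 0, state$h <= 1,
            state$n >= 0, state$n <= 1)
  v <- state$Vm
  # absolute currents (pA) -> uA/cm^2: 1 pA = 1e-6 uA
  pa2dens <- 1e-6 / params$area
  I_abs <- state$I_bias + I_syn - state$gAHP * (v - params$EK)
  (-params$gK_max * state$n^4 * (v - params$EK) -
     params$gNa_max * mod$scale_gNa * state$m^3 * state$h * (v - params$ENa) -
     params$gl * (v - params$El) +
     I_abs * pa2dens) / params$Cm
}

#' One step of the sAHP conductance
#'
#' The slow afterhyperpolarization conductance decays exponentially with
#' time constant `tauAHP` and is incremented by `alphaCa` (after the decay)
#' whenever the neuron emitted a spike during the step.
#'
#' @param gAHP Current sAHP conductance (nS); vectorized.
#' @param spiked Logical; did the neuron spike this step?
#' @param dt Step size (ms).
#' @param params A [neuron_params()].
#' @return Updated conductance (nS).
#' @export
sahp_step <- function(gAHP, spiked, dt, params) {
  stopifnot(all(gAHP >= 0), dt > 0)
  gAHP * exp(-dt / (params$tauAHP * 1000)) + ifelse(spiked, params$alphaCa, 0)
}

#' Membrane-noise increment
#'
#' One Euler-Maruyama noise increment per neuron. The amplitude is chosen so
#' that on a passive leak-only membrane the stationary standard deviation of
#' Vm equals `params$sigma` (Ornstein-Uhlenbeck scaling with relaxation rate
#' gl/Cm): dV = sigma * sqrt(2 * (gl/Cm) * dt) * N(0, 1).
#'
#' @param params A [neuron_params()].
#' @param dt Step size (ms).
#' @param n Number of independent draws.
#' @return Voltage increments (mV), length `n`.
#' @export
noise_increment <- function(params, dt, n = 1) {
  stopifnot(dt > 0)
  if (params$sigma == 0) return(rep(0, n))
  params$sigma * sqrt(2 * (params$gl / params$Cm) * dt) * stats::rnorm(n)
}

#' Heterogeneous bias currents
#'
#' Per-neuron constant applied currents drawn i.i.d. from a uniform
#' distribution on `[-9.5, 9.5]` pA, fixed for the whole simulation. This is
#' the only source of excitability heterogeneity in the network.
#'
#' @param N Number of neurons (>= 1).
#' @param lim Half-width of the uniform distribution (pA).
#' @return Numeric vector of length `N` (pA).
#' @export
draw_bias_currents <- function(N, lim = 9.5) {
  if (length(N) != 1 || is.na(N) || N < 1) {
    stop("N must be a single integer >= 1", call. = FALSE)
  }
  stats::runif(N, -lim, lim)
}

#' Deterministic resting state of an isolated neuron
#'
#' Root-finds the self-consistent resting potential of the full current
#' balance with gates at their steady-state values, zero noise, zero bias
#' and zero sAHP conductance. Used for simulation initial conditions.
#'
#' @param params A [neuron_params()].
#' @param mod A [rate_modifier()].
#' @return A list with `Vm` and steady-state `m`, `h`, `n`.
#' @export
resting_state <- function(params, mod = rate_modifier()) {
  f <- function(v) {
    g <- gate_steady_state(v, params$VT, mod)
    membrane_derivative(
      list(Vm = v, m = g$m, h = g$h, n = g$n, gAHP = 0, I_bias = 0),
      params, I_syn = 0, mod = mod
    )
  }
  # scan upward from EK for the first sign change, then refine
  grid <- seq(params$EK + 0.5, params$VT + 10, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  ix <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(ix) == 0) stop("no resting potential found in search interval",
                            call. = FALSE)
  root <- stats::uniroot(f, c(grid[ix[1]], grid[ix[1] + 1]), tol = 1e-10)$root
  g <- gate_steady_state(root, params$VT, mod)
  list(Vm = root, m = g$m, h = g$h, n = g$n)
}
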