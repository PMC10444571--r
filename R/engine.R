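#' Simulation configuration
#'
#' Collects everything a network simulation needs: durations, integration
#' step, recording rate, network geometry/connectivity options, neuron and
#' synapse parameters, the experimental condition, and the seed. Defaults
#' reproduce the control study conditions: 650 s simulated at dt = 0.1 ms
#' with the first 50 s discarded as transient, 100 neurons at 30%
#' connectivity, recorded by 12 virtual electrodes at 10 kHz.
#'
#' @param duration Total simulated time (s).
#' @param transient_discard Initial transient dropped from all outputs (s).
#' @param dt Integration step (ms).
#' @param record_rate Electrode sampling rate (kHz); `1/(record_rate) / dt`
#'   must be a whole number of steps.
#' @param n_networks Number of independent networks in a batch.
#' @param seed Master seed (integer).
#' @param condition A [condition_spec()].
#' @param neuron A [neuron_params()].
#' @param synapse A [synapse_params()].
#' @param N,p_connect,pitch,velocity,lambda,cutoff Network construction
#'   options, see [build_network()].
#' @param spike_threshold Membrane potential (mV) whose upward crossing
#'   registers a ground-truth spike.
#' @param refractory Spike-registration lockout (ms).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(duration = 650, transient_discard = 50,
                              dt = 0.1, record_rate = 10, n_networks = 12,
                              seed = 1, condition = condition_spec("control"),
                              neuron = neuron_params(),
                              synapse = synapse_params(),
                              N = 100, p_connect = 0.3, pitch = 100,
                              velocity = 200, lambda = 30, cutoff = 300,
                              spike_threshold = 0, refractory = 3) {
  cfg <- list(duration = duration, transient_discard = transient_discard,
              dt = dt, record_rate = record_rate, n_networks = n_networks,
              seed = as.integer(seed), condition = condition,
              neuron = neuron, synapse = synapse,
              N = N, p_connect = p_connect, pitch = pitch,
              velocity = velocity, lambda = lambda, cutoff = cutoff,
              spike_threshold = spike_threshold, refractory = refractory)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (!(cfg$duration > cfg$transient_discard)) {
    stop("duration must exceed transient_discard", call. = FALSE)
  }
  stopifnot(cfg$dt > 0, cfg$record_rate > 0, cfg$n_networks >= 1,
            cfg$N >= 2, cfg$refractory >= 0)
  stride <- 1 / cfg$record_rate / cfg$dt
  if (abs(stride - round(stride)) > 1e-9) {
    stop("dt must divide the recording interval (1/record_rate)",
         call. = FALSE)
  }
  validate_neuron_params(cfg$neuron)
  validate_synapse_params(cfg$synapse)
  invisible(cfg)
}

#' Experimental condition
#'
#' Named parameter-override sets mirroring the in-vitro pharmacology and the
#' Dravet-syndrome (DS) model:
#' \describe{
#'   \item{control}{no change.}
#'   \item{sAHP_half}{sAHP increment `alphaCa` halved (linopirdine analog:
#'     partial block of the potassium channels underlying the sAHP).}
#'   \item{Na_block}{sodium conductance set to zero (TTX analog).}
#'   \item{NMDA_block}{NMDA conductance set to zero (MK-801 analog).}
#'   \item{AMPA_block}{AMPA conductance set to zero (NBQX/NASPM analog).}
#'   \item{DS}{the Dravet-syndrome override set: reduced sAHP, reduced
#'     synaptic scaling, reduced short-term depression, slowed sodium
#'     activation kinetics. Factors are exposed and overridable.}
#'   \item{sodium_mod}{an arbitrary sodium-channel modification given as a
#'     [rate_modifier()] via `modifier`.}
#' }
#'
#' @param name Condition name.
#' @param modifier A [rate_modifier()], used by `sodium_mod` (and appended
#'   to the DS set when supplied there).
#' @param alphaCa_factor,S_factor,U_factor,na_rate_factor DS override
#'   factors on the sAHP increment, synaptic scaling, STD utilization, and
#'   sodium activation-gate rate constants.
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(name = c("control", "sAHP_half", "Na_block",
                                    "NMDA_block", "AMPA_block", "DS",
                                    "sodium_mod"),
                           modifier = rate_modifier(),
                           alphaCa_factor = 0.4, S_factor = 0.38,
                           U_factor = 0.1, na_rate_factor = 0.7) {
  name <- match.arg(name)
  structure(list(name = name, modifier = modifier,
                 alphaCa_factor = alphaCa_factor, S_factor = S_factor,
                 U_factor = U_factor, na_rate_factor = na_rate_factor),
            class = "condition_spec")
}

#' Apply an experimental condition to parameter sets
#'
#' @param neuron A [neuron_params()].
#' @param synapse A [synapse_params()].
#' @param condition A [condition_spec()] (or a condition name).
#' @return A list with modified `neuron`, `synapse` and the effective
#'   [rate_modifier()].
#' @export
apply_condition <- function(neuron, synapse, condition) {
  if (is.character(condition)) condition <- condition_spec(condition)
  if (!inherits(condition, "condition_spec")) {
    stop("unknown condition", call. = FALSE)
  }
  mod <- rate_modifier()
  switch(condition$name,
    control = NULL,
    sAHP_half = { neuron$alphaCa <- neuron$alphaCa * 0.5 },
    Na_block = { neuron$gNa_max <- 0 },
    NMDA_block = { synapse$gNMDA_max <- 0 },
    AMPA_block = { synapse$gAMPA_max <- 0 },
    sodium_mod = { mod <- condition$modifier },
    DS = {
      neuron$alphaCa <- neuron$alphaCa * condition$alphaCa_factor
      synapse$S <- synapse$S * condition$S_factor
      synapse$U <- synapse$U * condition$U_factor
      mod <- condition$modifier
      mod$scale_alpha_m <- mod$scale_alpha_m * condition$na_rate_factor
      mod$scale_beta_m <- mod$scale_beta_m * condition$na_rate_factor
    },
    stop("unknown condition: ", condition$name, call. = FALSE)
  )
  list(neuron = neuron, synapse = synapse, modifier = mod)
}

#' Run one network simulation
#'
#' Builds (or reuses) a network layout, applies the configured condition,
#' and integrates the full model. Gating variables use exponential Euler;
#' the membrane potential uses forward Euler with an Euler-Maruyama noise
#' term. All randomness (connectivity, weights, bias currents, membrane
#' noise) derives from `config$seed` plus `network_id`, so a rerun with the
#' same configuration is bit-identical, and different conditions run with
#' the same seed share connectivity, weights and heterogeneity (paired
#' designs).
#'
#' @param config A [simulation_config()].
#' @param network Optional pre-built [build_network()] layout to reuse
#'   (paired conditions); when `NULL` one is drawn from the seed.
#' @param network_id Integer tag; offsets the seed so networks in a batch
#'   are independent.
#' @return An object of class `mea_simulation`: list with `signals`
#'   (electrode x sample matrix, retained window only), `fs` (Hz), `spikes`
#'   (tibble `neuron`, `time` in s relative to the retained window),
#'   `duration` (retained, s), `network`, `config`, `network_id`.
#' @export
run_simulation <- function(config, network = NULL, network_id = 1L) {
  validate_config(config)
  child_seed <- derive_seed(config$seed, network_id)
  if (is.null(network)) {
    network <- local_seeded(child_seed, build_network(
      N = config$N, p_connect = config$p_connect, pitch = config$pitch,
      velocity = config$velocity, dt = config$dt, lambda = config$lambda,
      cutoff = config$cutoff))
  }
  pars <- apply_condition(config$neuron, config$synapse, config$condition)
  rest <- resting_state(pars$neuron, pars$modifier)

  n_steps <- as.integer(round(config$duration * 1000 / config$dt))
  transient_steps <- as.integer(round(config$transient_discard * 1000 /
                                        config$dt))
  stride <- as.integer(round(1 / config$record_rate / config$dt))

  raw <- .simulate_network_cpp(
    neuron = unclass(pars$neuron), synapse = unclass(pars$synapse),
    mod = unclass(pars$modifier),
    edge_from = as.integer(network$edges$from - 1L),
    edge_to = as.integer(network$edges$to - 1L),
    edge_weight = network$edges$weight,
    edge_delay_steps = as.integer(network$edges$delay_steps),
    bias = network$bias, elec_w = network$electrode_weights,
    dt = config$dt, n_steps = n_steps, transient_steps = transient_steps,
    record_stride = stride,
    v_init = rest$Vm, m_init = rest$m, h_init = rest$h, n_init = rest$n,
    spike_threshold = config$spike_threshold,
    refractory_steps = as.integer(round(config$refractory / config$dt)),
    rng_seed = child_seed
  )

  t_all <- raw$spike_step * config$dt / 1000 - config$transient_discard
  keep <- t_all >= 0
  spikes <- tibble::tibble(neuron = raw$spike_neuron[keep],
                           time = t_all[keep])
  structure(
    list(signals = raw$signals,
         fs = config$record_rate * 1000,
         spikes = spikes,
         duration = config$duration - config$transient_discard,
         network = network,
         config = config,
         network_id = as.integer(network_id)),
    class = "mea_simulation"
  )
}

# deterministic master-seed -> child-seed spawning; stays well below 2^31
derive_seed <- function(master, network_id) {
  (as.integer(master) * 1009L + as.integer(network_id) * 9973L) %% 2147483L
}

# evaluate expr with a locally seeded RNG, restoring the caller's state
local_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.mea_simulation <- function(x, ...) {
  cat("<mea_simulation>", x$network$N, "neurons,",
      nrow(x$spikes), "spikes in", x$duration, "s retained window;",
      "condition:", x$config$condition$name,
      "(network", paste0(x$network_id, ")"), "\n")
  invisible(x)
}

#' Run matched simulations under several conditions
#'
#' Simulates `n_networks` baseline networks, then re-simulates each network
#' under every requested condition with matched seed, connectivity, weights
#' and heterogeneity, so per-network paired comparisons are possible.
#'
#' @param conditions Character vector of condition names or a named list of
#'   [condition_spec()] objects (a `control` baseline is always run).
#' @param config A [simulation_config()]; its `n_networks` and `condition`
#'   fields are overridden per run.
#' @param n_networks Number of matched networks per condition.
#' @param keep `"features"` (default) analyzes each run with the MEA chain
#'   and keeps only the feature row; `"simulations"` also returns the raw
#'   simulation objects (memory-heavy).
#' @return A tibble with one row per (condition, network): `condition`,
#'   `network`, `seed`, `n_bursts`, `NBR`, `NBD`, `PSIB`, `MFR`. With
#'   `keep = "simulations"` the tibble carries a `sims` attribute.
#' @export
run_condition_battery <- function(conditions, config = simulation_config(),
                                  n_networks = config$n_networks,
                                  keep = c("features", "simulations")) {
  keep <- match.arg(keep)
  conditions <- normalize_conditions(conditions)
  if (!"control" %in% names(conditions)) {
    conditions <- c(list(control = condition_spec("control")), conditions)
  }
  sims <- list()
  rows <- list()
  for (i in seq_len(n_networks)) {
    base_cfg <- config
    base_cfg$condition <- conditions[["control"]]
    base <- run_simulation(base_cfg, network_id = i)
    net <- base$network
    for (cn in names(conditions)) {
      sim <- if (cn == "control") base else {
        cfg <- config
        cfg$condition <- conditions[[cn]]
        run_simulation(cfg, network = net, network_id = i)
      }
      feats <- glance(analyze_simulation(sim))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(condition = cn, network = i,
                       seed = derive_seed(config$seed, i)),
        feats
      )
      if (keep == "simulations") sims[[paste(cn, i, sep = "_")]] <- sim
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep == "simulations") attr(out, "sims") <- sims
  out
}

normalize_conditions <- function(conditions) {
  if (is.character(conditions)) {
    specs <- lapply(conditions, condition_spec)
    names(specs) <- conditions
    specs
  } else if (is.list(conditions)) {
    if (is.null(names(conditions)) || any(names(conditions) == "")) {
      names(conditions) <- vapply(conditions, function(x) x$name,
                                  character(1))
    }
    conditions
  } else stop("conditions must be names or condition_spec objects",
              call. = FALSE)
}

#' Scan sodium-channel modifications
#'
#' Runs every supplied [rate_modifier()] (plus any full [condition_spec()],
#' e.g. the DS override set) on matched networks against a shared control
#' baseline, and reports per-modification burst features and their
#' normalized (condition / matched control) means.
#'
#' @param modifiers Named list of [rate_modifier()] and/or
#'   [condition_spec()] objects.
#' @param config A [simulation_config()].
#' @param n_networks Matched networks per modification.
#' @param deadband Relative deadband for calling a direction: a feature
#'   counts as decreased when its normalized mean < 1 - deadband, increased
#'   when > 1 + deadband.
#' @return A tibble, one row per modification: normalized `NBR_norm`,
#'   `NBD_norm`, `PSIB_norm` (condition / control, averaged over matched
#'   networks), raw means, and logical flags `nbr_down`, `nbd_up`,
#'   `psib_down`, `ds_like` (all three at once).
#' @export
sodium_scan <- function(modifiers, config = simulation_config(),
                        n_networks = 2, deadband = 0.05) {
  stopifnot(length(modifiers) > 0)
  specs <- lapply(modifiers, function(m) {
    if (inherits(m, "condition_spec")) m
    else if (inherits(m, "rate_modifier")) {
      condition_spec("sodium_mod", modifier = m)
    } else stop("modifiers must be rate_modifier or condition_spec objects",
                call. = FALSE)
  })
  if (is.null(names(specs))) names(specs) <- paste0("mod", seq_along(specs))
  tab <- run_condition_battery(specs, config = config,
                               n_networks = n_networks)
  summarize_scan(tab, deadband)
}

summarize_scan <- function(tab, deadband = 0.05) {
  base <- dplyr::filter(tab, .data$condition == "control")
  norm <- tab |>
    dplyr::filter(.data$condition != "control") |>
    dplyr::left_join(base, by = "network", suffix = c("", "_ctrl")) |>
    dplyr::mutate(
      NBR_ratio = .data$NBR / .data$NBR_ctrl,
      NBD_ratio = .data$NBD / .data$NBD_ctrl,
      PSIB_ratio = .data$PSIB / .data$PSIB_ctrl
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      NBR_norm = mean(.data$NBR_ratio, na.rm = TRUE),
      NBD_norm = mean(.data$NBD_ratio, na.rm = TRUE),
      PSIB_norm = mean(.data$PSIB_ratio, na.rm = TRUE),
      NBR = mean(.data$NBR), NBD = mean(.data$NBD, na.rm = TRUE),
      PSIB = mean(.data$PSIB), MFR = mean(.data$MFR),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      # a silent network (no bursts at all) counts as NBR down but cannot
      # show an NBD increase: its duration is undefined, not longer
      nbr_down = .data$NBR_norm < 1 - deadband,
      nbd_up = !is.na(.data$NBD_norm) & .data$NBD_norm > 1 + deadband,
      psib_down = .data$PSIB_norm < 1 - deadband,
      ds_like = .data$nbr_down & .data$nbd_up & .data$psib_down
    )
  norm
}
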