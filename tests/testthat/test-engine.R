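test_that("conditions map onto the documented parameter overrides", {
  np <- neuron_params(); sp <- synapse_params()
  ctl <- apply_condition(np, sp, condition_spec("control"))
  expect_equal(ctl$neuron, np)
  expect_equal(ctl$synapse, sp)

  half <- apply_condition(np, sp, "sAHP_half")
  expect_equal(half$neuron$alphaCa, 0.00175)
  expect_equal(half$neuron[names(half$neuron) != "alphaCa"],
               unclass(np)[names(np) != "alphaCa"])

  expect_equal(apply_condition(np, sp, "Na_block")$neuron$gNa_max, 0)
  expect_equal(apply_condition(np, sp, "NMDA_block")$synapse$gNMDA_max, 0)
  expect_equal(apply_condition(np, sp, "AMPA_block")$synapse$gAMPA_max, 0)

  ds <- apply_condition(np, sp, condition_spec("DS"))
  expect_equal(ds$neuron$alphaCa, np$alphaCa * 0.4)
  expect_equal(ds$synapse$S, 0.38)
  expect_equal(ds$synapse$U, 0.015 * 0.1)
  expect_equal(ds$modifier$scale_alpha_m, 0.7)
  expect_equal(ds$modifier$scale_beta_m, 0.7)
  # factors are exposed and overridable
  ds2 <- apply_condition(np, sp, condition_spec("DS", S_factor = 0.5))
  expect_equal(ds2$synapse$S, 0.5)

  expect_error(apply_condition(np, sp, "linopirdine"))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(duration = 40, transient_discard = 50),
               "duration")
  expect_error(simulation_config(dt = 0.3, record_rate = 10),
               "recording interval")
  expect_silent(validate_config(simulation_config(duration = 650,
                                                  n_networks = 12)))
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  s1 <- run_simulation(cfg, network_id = 2)
  s2 <- run_simulation(cfg, network_id = 2)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$signals, s2$signals)
  # a different network id gives a different realization
  s3 <- run_simulation(cfg, network_id = 3)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("a quiescent configuration produces no spikes and a sodium block silences everything", {
  # no noise, no synapses, bias far below rheobase
  cfg <- tiny_config(seed = 1, N = 10, p_connect = 0,
                     neuron = neuron_params(sigma = 0))
  net <- local({ set.seed(8); build_network(N = 10, p_connect = 0) })
  net$bias <- rep(2, 10)  # pA, well under rheobase
  sim <- run_simulation(cfg, network = net)
  expect_equal(nrow(sim$spikes), 0)

  # full network with noise, but sodium channels blocked: no spikes at all
  cfg2 <- tiny_config(seed = 5, condition = condition_spec("Na_block"))
  sim2 <- run_simulation(cfg2)
  expect_equal(nrow(sim2$spikes), 0)

  # engine consistency with the analytic rate functions: started exactly at
  # the R-computed resting state with zero noise and bias, the integrator
  # (lookup-table rates) must hold the fixed point
  net0 <- local({ set.seed(6); build_network(N = 10, p_connect = 0) })
  net0$bias <- rep(0, 10)
  sim0 <- run_simulation(tiny_config(seed = 1, N = 10, p_connect = 0,
                                     duration = 6, transient = 1,
                                     neuron = neuron_params(sigma = 0)),
                         network = net0)
  rest_sig <- sim0$signals[rowSums(net0$electrode_weights) > 0, , drop = FALSE]
  drift <- apply(rest_sig, 1, function(x) max(abs(x - x[1])))
  expect_lt(max(drift / abs(rest_sig[, 1])), 1e-4)
})

test_that("signal dimensions follow duration, transient and sampling rate", {
  cfg <- tiny_config(duration = 5, transient = 2, seed = 2, N = 12)
  sim <- run_simulation(cfg)
  expect_equal(dim(sim$signals), c(12, 3 * 10000))
  expect_equal(sim$duration, 3)
  expect_true(all(sim$spikes$time >= 0 & sim$spikes$time < 3))
})

test_that("paired batteries reuse the baseline network for each condition", {
  cfg <- tiny_config(seed = 13)
  tab <- run_condition_battery(c("AMPA_block"), config = cfg,
                               n_networks = 2, keep = "simulations")
  expect_equal(nrow(tab), 4)  # 2 conditions x 2 networks
  expect_setequal(unique(tab$condition), c("control", "AMPA_block"))
  sims <- attr(tab, "sims")
  # matched pair shares adjacency, weights and bias exactly
  expect_identical(sims$control_1$network$edges,
                   sims$AMPA_block_1$network$edges)
  expect_identical(sims$control_1$network$bias,
                   sims$AMPA_block_1$network$bias)
  expect_false(identical(sims$control_1$network$edges,
                         sims$control_2$network$edges))
  # feature rows are reproducible from the stored simulations
  f <- glance(analyze_simulation(sims$control_1))
  expect_equal(tab$MFR[tab$condition == "control" & tab$network == 1],
               f$MFR)
})

test_that("simulation results round-trip through disk", {
  skip_if_not_installed("arrow")
  cfg <- tiny_config(duration = 4, transient = 2, seed = 31, N = 12)
  sim <- run_simulation(cfg)
  dir <- withr::local_tempdir()
  write_result(sim, dir)
  back <- read_result(dir)
  expect_equal(back$spikes$neuron, sim$spikes$neuron)
  expect_equal(back$spikes$time, sim$spikes$time, tolerance = 1e-12)
  expect_equal(back$signals, sim$signals, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$meta$seed, cfg$seed)
  expect_equal(back$meta$condition, "control")
  expect_error(read_result(file.path(dir, "nope")), "missing or corrupt")
})

test_that("a larger network at matched expected in-degree still bursts", {
  # N up, connection probability down proportionally (in-degree fixed at 30)
  base <- simulation_config(duration = 80, transient_discard = 50, seed = 3,
                            N = 100, p_connect = 0.3)
  big <- simulation_config(duration = 80, transient_discard = 50, seed = 3,
                           N = 150, p_connect = 0.2)
  f_base <- glance(analyze_simulation(run_simulation(base, network_id = 1)))
  f_big <- glance(analyze_simulation(run_simulation(big, network_id = 1)))
  expect_gt(f_base$n_bursts, 0)
  expect_gt(f_big$n_bursts, 0)
})

test_that("halving dt changes burst-level behavior only mildly (scheme stability)", {
  # moderately sized network so bursts occur within a short window
  mk <- function(dt) {
    cfg <- simulation_config(duration = 30, transient_discard = 10,
                             dt = dt, seed = 9, N = 100)
    glance(analyze_simulation(run_simulation(cfg, network_id = 1)))
  }
  f1 <- mk(0.1)
  f2 <- mk(0.05)
  expect_gt(f1$n_bursts, 0)
  expect_gt(f2$n_bursts, 0)
  # burst rates agree within one burst count over the 20 s window
  expect_lt(abs(f1$n_bursts - f2$n_bursts), 2)
})
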