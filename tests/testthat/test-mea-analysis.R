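test_that("the band-pass filter passes 1 kHz and rejects DC and 10 Hz", {
  fs <- 10000
  t <- seq(0, 2, by = 1 / fs)[-1]
  # DC: output settles to ~0
  dc <- bandpass_filter(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[1, (fs / 2):length(t)])), 1e-3)
  # 1 kHz (mid-band): steady-state amplitude within 1 dB of unity
  s1k <- bandpass_filter(sin(2 * pi * 1000 * t), fs)
  amp <- max(abs(s1k[1, (fs):(2 * fs - 1)]))
  expect_lt(abs(20 * log10(amp)), 1)
  # 10 Hz: attenuated by more than 20 dB
  s10 <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  amp10 <- max(abs(s10[1, (fs):(2 * fs - 1)]))
  expect_lt(20 * log10(amp10), -20)
  expect_error(bandpass_filter(rep(0, 100), fs = 7000), "sampling rate")
})

test_that("spike detection finds exactly the injected impulses and nothing on silence", {
  fs <- 10000
  expect_equal(nrow(detect_spikes(matrix(0, 2, fs), fs)), 0)

  set.seed(61)
  noise <- stats::rnorm(60 * fs, sd = 1)
  spike_at <- sort(sample.int(60 * fs - 100, 20))
  spike_at <- spike_at[c(TRUE, diff(spike_at) > 0.05 * fs)]  # separated
  x <- noise
  x[spike_at] <- 10 * sqrt(mean(noise^2))
  sp <- detect_spikes(matrix(x, 1), fs, thr_factor = 4)
  got <- sp$time[sp$electrode == 1]
  # every injected impulse recovered (noise itself rarely crosses 4xRMS,
  # extra noise events are tolerated up to the analytic tail expectation)
  inj <- (spike_at - 1) / fs
  expect_true(all(vapply(inj, function(ti) any(abs(got - ti) < 1e-3),
                         logical(1))))
  # false positives bounded by ~2x the Gaussian-tail crossing expectation
  p_tail <- 2 * stats::pnorm(-4)
  expect_lt(nrow(sp) - length(inj), 2 * p_tail * 60 * fs + 10)
})

test_that("network-burst detection recovers a hand-built periodic raster", {
  # 12 electrodes firing 200 Hz for 500 ms every 10 s over 100 s
  windows <- tibble::tibble(start = seq(0.5, 95, by = 10),
                            end = seq(1.0, 95.5, by = 10))
  spikes <- regular_burst_raster(100, 12, windows)
  bursts <- detect_network_bursts(spikes)
  expect_equal(nrow(bursts), 10)
  expect_equal(bursts$end - bursts$start, rep(0.5, 10), tolerance = 0.1)
  expect_equal(bursts$start, windows$start, tolerance = 0.05)

  # empty input: empty burst set
  empty <- measim:::new_spike_trains(
    tibble::tibble(electrode = integer(), time = numeric()), 10, 12)
  expect_equal(nrow(detect_network_bursts(empty)), 0)
})

test_that("bursts dominated by one electrode are excluded", {
  # burst where 85% of spikes sit on electrode 1
  t_burst <- seq(2, 2.3, by = 0.002)          # 151 spikes on electrode 1
  others <- lapply(2:12, function(e)
    tibble::tibble(electrode = e, time = seq(2.05, 2.25, by = 0.1)))  # 3 each
  spikes <- measim:::new_spike_trains(
    dplyr::bind_rows(tibble::tibble(electrode = 1L, time = t_burst), others),
    10, 12)
  counts <- table(spikes$electrode)
  expect_gt(counts[["1"]] / sum(counts), 0.8)
  bursts <- detect_network_bursts(spikes)
  expect_equal(nrow(bursts), 0)
  expect_gte(attr(bursts, "n_excluded"), 1)
})

test_that("feature arithmetic matches its definitions", {
  windows <- tibble::tibble(start = seq(10, 600, by = 60)[1:10],
                            end = seq(10.5, 600, by = 60)[1:10])
  spikes <- regular_burst_raster(600, 12, windows, rate_in = 100)
  bursts <- detect_network_bursts(spikes)
  f <- compute_features(spikes, bursts)
  expect_equal(f$NBR, 10 / 600 * 60)           # 1 burst per minute
  expect_equal(f$PSIB, 100, tolerance = 0.5)   # every spike inside a burst
  expect_equal(f$NBD, 0.5, tolerance = 0.1)

  # MFR: 7200 spikes over 12 electrodes x 600 s = 1 spike/s
  even <- measim:::new_spike_trains(
    tibble::tibble(electrode = rep(1:12, each = 600),
                   time = rep(seq(0.5, 599.5, by = 1), 12)),
    600, 12)
  f2 <- compute_features(even, detect_network_bursts(even))
  expect_equal(f2$MFR, 1)

  # zero bursts: NBD missing, NBR and PSIB zero
  sparse <- measim:::new_spike_trains(
    tibble::tibble(electrode = 1L, time = c(1, 5, 9)), 10, 12)
  f3 <- compute_features(sparse, detect_network_bursts(sparse))
  expect_true(is.na(f3$NBD))
  expect_equal(f3$NBR, 0)
})

test_that("features are invariant under electrode permutation", {
  set.seed(19)
  spikes <- synth_raster(60, 12, background_rate = 0.5,
                         epochs = tibble::tibble(
                           start = c(10, 30, 50), end = c(10.4, 30.4, 50.4),
                           rate = 150))
  perm <- sample(12)
  permuted <- measim:::new_spike_trains(
    dplyr::mutate(tibble::as_tibble(spikes), electrode = perm[electrode]),
    attr(spikes, "duration"), 12)
  f1 <- compute_features(spikes, detect_network_bursts(spikes))
  f2 <- compute_features(permuted, detect_network_bursts(permuted))
  expect_equal(f1, f2)
})

test_that("the synthetic raster is seeded, and its ground truth is recovered by the detector", {
  set.seed(55)
  a <- synth_raster(30, 12, 0.3)
  set.seed(55)
  b <- synth_raster(30, 12, 0.3)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))

  # background only (sparse, in vitro-like): essentially nothing in bursts
  set.seed(56)
  bg <- synth_raster(120, 12, background_rate = 0.3)
  f <- compute_features(bg, detect_network_bursts(bg))
  expect_lt(f$PSIB, 10)

  # zero background, 5 epochs: detector recovers all 5 intervals
  epochs <- tibble::tibble(start = c(5, 25, 45, 65, 85),
                           end = c(5.5, 25.5, 45.5, 65.5, 85.5), rate = 150)
  set.seed(57)
  sp <- synth_raster(100, 12, background_rate = 0, epochs = epochs,
                     jitter = 0.002)
  bursts <- detect_network_bursts(sp)
  expect_equal(nrow(bursts), 5)
  expect_equal(bursts$start, epochs$start, tolerance = 0.05)
})

test_that("PSIB rises monotonically as the background rate vanishes", {
  epochs <- tibble::tibble(start = c(20, 60, 100), end = c(20.5, 60.5, 100.5),
                           rate = 200)
  psib <- vapply(c(2, 0.5, 0.05), function(bg) {
    set.seed(71)
    sp <- synth_raster(120, 12, background_rate = bg, epochs = epochs)
    compute_features(sp, detect_network_bursts(sp))$PSIB
  }, numeric(1))
  expect_true(all(diff(psib) > 0))
})

test_that("the detector matches generator ground truth across 100 random fixtures", {
  set.seed(123)
  n_match <- 0
  for (i in 1:100) {
    n_ep <- sample(2:6, 1)
    dur <- 60
    # epochs well separated and much hotter than background
    starts <- sort(stats::runif(n_ep, 2, dur - 4))
    while (any(diff(starts) < 6)) {
      starts <- sort(stats::runif(n_ep, 2, dur - 4))
    }
    epochs <- tibble::tibble(start = starts,
                             end = starts + stats::runif(n_ep, 0.3, 0.8),
                             rate = stats::runif(n_ep, 120, 250))
    bg <- stats::runif(1, 0, 1)   # epochs are always > 8x background
    sp <- synth_raster(dur, 12, background_rate = bg, epochs = epochs,
                       jitter = 0.002)
    bursts <- detect_network_bursts(sp)
    if (nrow(bursts) == n_ep) n_match <- n_match + 1
  }
  expect_equal(n_match, 100)
})
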