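#' Band-pass filter multichannel electrode signals
#'
#' Fifth-order Butterworth band-pass (100-3500 Hz by default), applied
#' forward (causally) per channel, as for extracellular MEA recordings
#' before spike detection.
#'
#' @param signals Channel x sample numeric matrix (or a vector for one
#'   channel).
#' @param fs Sampling rate (Hz); must exceed twice the upper corner.
#' @param low,high Pass-band corners (Hz).
#' @param order Butterworth order.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(signals, fs, low = 100, high = 3500, order = 5) {
  if (fs <= 2 * high) {
    stop("sampling rate must exceed twice the upper pass-band corner",
         call. = FALSE)
  }
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- signals
  for (ch in seq_len(nrow(signals))) {
    out[ch, ] <- signal::filter(bf, signals[ch, ])
  }
  out
}

#' Threshold-based spike detection
#'
#' Per channel, the detection threshold is `thr_factor` times the root mean
#' square of the whole filtered trace. An event is registered at the first
#' sample whose absolute value exceeds the threshold; subsequent
#' suprathreshold samples within the dead time are attributed to the same
#' event. The absolute-value criterion makes the detector polarity-agnostic
#' (in vitro spikes are negative-going, virtual-electrode spikes positive).
#'
#' @param signals Filtered channel x sample matrix.
#' @param fs Sampling rate (Hz).
#' @param thr_factor Threshold in multiples of the trace RMS.
#' @param dead_time Per-channel dead time between events (s).
#' @return A `spike_trains` tibble with columns `electrode`, `time` (s),
#'   carrying `duration` and `n_electrodes` attributes.
#' @export
detect_spikes <- function(signals, fs, thr_factor = 4, dead_time = 0.002) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  min_gap <- max(1L, as.integer(round(dead_time * fs)))
  rows <- lapply(seq_len(nrow(signals)), function(ch) {
    x <- signals[ch, ]
    thr <- thr_factor * sqrt(mean(x^2))
    if (thr == 0) return(NULL)
    idx <- which(abs(x) > thr)
    if (length(idx) == 0) return(NULL)
    idx <- .enforce_dead_time_cpp(idx, min_gap)
    tibble::tibble(electrode = ch, time = (idx - 1) / fs)
  })
  spikes <- dplyr::bind_rows(rows)
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(electrode = integer(), time = numeric())
  }
  new_spike_trains(spikes, duration = ncol(signals) / fs,
                   n_electrodes = nrow(signals))
}

new_spike_trains <- function(spikes, duration, n_electrodes) {
  spikes <- dplyr::arrange(spikes, .data$electrode, .data$time)
  structure(spikes, duration = duration, n_electrodes = n_electrodes,
            class = c("spike_trains", class(spikes)))
}

#' Network-burst detection from pooled spike trains
#'
#' The population spike rate is estimated by counting spikes from all
#' electrodes in `bin` s bins and smoothing with a centered moving average
#' over `smooth_bins` bins. A burst opens at the start of a run of bins
#' that stays at or above 1/4 of the recording's maximum smoothed rate for
#' at least `sustain` s, and closes at the first bin that falls below
#' 1/100 of the maximum rate. A detected burst is discarded when more than
#' `exclusion` (80%) of its spikes originate from a single electrode.
#'
#' @param spikes A `spike_trains` object (or tibble with `electrode`,
#'   `time`).
#' @param duration Recording duration (s); taken from `spikes` when absent.
#' @param bin Rate-estimation bin width (s).
#' @param smooth_bins Moving-average width (bins, odd).
#' @param open_frac,close_frac Opening/closing thresholds as fractions of
#'   the maximum smoothed rate.
#' @param sustain Minimum time the rate must stay above the opening
#'   threshold (s).
#' @param exclusion Maximum tolerated fraction of burst spikes from one
#'   electrode.
#' @return A `network_bursts` tibble with columns `start`, `end` (s) and
#'   `n_spikes`; the per-electrode spike counts of each burst are kept in
#'   the `electrode_counts` attribute (matrix bursts x electrodes), and
#'   the number of bursts removed by the single-electrode rule in the
#'   `n_excluded` attribute.
#' @export
detect_network_bursts <- function(spikes, duration = attr(spikes, "duration"),
                                  bin = 0.01, smooth_bins = 3,
                                  open_frac = 1 / 4, close_frac = 1 / 100,
                                  sustain = 0.06, exclusion = 0.8) {
  if (is.null(duration)) stop("duration required", call. = FALSE)
  n_electrodes <- attr(spikes, "n_electrodes")
  if (is.null(n_electrodes)) n_electrodes <- max(spikes$electrode, 1)
  empty <- new_network_bursts(
    tibble::tibble(start = numeric(), end = numeric(), n_spikes = integer()),
    matrix(0, 0, n_electrodes), 0L
  )
  if (nrow(spikes) == 0) return(empty)

  n_bins <- max(1L, as.integer(ceiling(duration / bin)))
  counts <- tabulate(pmin(n_bins, floor(spikes$time / bin) + 1L), n_bins)
  rate <- as.numeric(stats::filter(counts, rep(1 / smooth_bins, smooth_bins),
                                   sides = 2))
  rate[is.na(rate)] <- counts[is.na(rate)] # edges: unsmoothed
  open_thr <- max(rate) * open_frac
  close_thr <- max(rate) * close_frac
  sustain_bins <- max(1L, as.integer(round(sustain / bin)))

  above_open <- rate >= open_thr
  # run lengths of consecutive bins above the opening threshold
  r <- rle(above_open)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  starts <- integer(); ends <- integer()
  in_progress_end <- 0L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < sustain_bins) next
    s <- run_start[k]
    if (s <= in_progress_end) next   # swallowed by the previous burst
    # close at the first bin below the close threshold after the run
    e <- run_end[k] + 1L
    while (e <= n_bins && rate[e] >= close_thr) e <- e + 1L
    starts <- c(starts, s)
    ends <- c(ends, e)
    in_progress_end <- e
  }
  if (length(starts) == 0) return(empty)

  start_t <- (starts - 1) * bin
  end_t <- pmin((ends - 1) * bin, duration)
  ecounts <- matrix(0L, length(starts), n_electrodes)
  n_spk <- integer(length(starts))
  for (b in seq_along(starts)) {
    inb <- spikes$time >= start_t[b] & spikes$time < end_t[b]
    n_spk[b] <- sum(inb)
    ecounts[b, ] <- tabulate(spikes$electrode[inb], n_electrodes)
  }
  dominant <- apply(ecounts, 1, max) / pmax(n_spk, 1L)
  keep <- n_spk > 0 & dominant <= exclusion
  new_network_bursts(
    tibble::tibble(start = start_t[keep], end = end_t[keep],
                   n_spikes = n_spk[keep]),
    ecounts[keep, , drop = FALSE],
    sum(!keep)
  )
}

new_network_bursts <- function(tab, ecounts, n_excluded) {
  structure(tab, electrode_counts = ecounts,
            n_excluded = as.integer(n_excluded),
            class = c("network_bursts", class(tab)))
}

#' Burst and firing features of a recording
#'
#' @param spikes A `spike_trains` object.
#' @param bursts A `network_bursts` object for the same recording.
#' @param duration Recording duration (s).
#' @param n_electrodes Number of electrodes.
#' @return A one-row tibble: `n_bursts`, `NBR` (bursts/min), `NBD` (mean
#'   burst duration, s; `NA` when there are no bursts), `PSIB` (% of all
#'   spikes inside bursts), `MFR` (spikes/s per electrode).
#' @export
compute_features <- function(spikes, bursts,
                             duration = attr(spikes, "duration"),
                             n_electrodes = attr(spikes, "n_electrodes")) {
  stopifnot(!is.null(duration), !is.null(n_electrodes), duration > 0)
  n_b <- nrow(bursts)
  total <- nrow(spikes)
  inside <- if (n_b == 0 || total == 0) 0L else {
    # bursts are ordered and non-overlapping: odd findInterval strata are
    # inside [start, end)
    breaks <- as.vector(rbind(bursts$start, bursts$end))
    sum(findInterval(spikes$time, breaks) %% 2 == 1)
  }
  tibble::tibble(
    n_bursts = n_b,
    NBR = n_b / duration * 60,
    NBD = if (n_b == 0) NA_real_ else mean(bursts$end - bursts$start),
    PSIB = if (total == 0) 0 else 100 * inside / total,
    MFR = total / (n_electrodes * duration)
  )
}

#' Full MEA analysis chain on multichannel voltage signals
#'
#' Band-pass filter, RMS-threshold spike detection, network-burst detection
#' and feature extraction. Exactly the same code path serves in-vitro-style
#' recordings and virtual-electrode simulator output.
#'
#' @param signals Channel x sample voltage matrix.
#' @param fs Sampling rate (Hz).
#' @param ... Passed on to the chain stages ([detect_spikes()],
#'   [detect_network_bursts()] parameters).
#' @return An object of class `mea_analysis`: list with `spikes`, `bursts`,
#'   `features`, `duration`, `n_electrodes`.
#' @export
analyze_recording <- function(signals, fs, ...) {
  dots <- list(...)
  filt <- bandpass_filter(signals, fs,
                          low = dots$low %||% 100,
                          high = dots$high %||% 3500,
                          order = dots$order %||% 5)
  spikes <- detect_spikes(filt, fs,
                          thr_factor = dots$thr_factor %||% 4,
                          dead_time = dots$dead_time %||% 0.002)
  analyze_spike_trains(spikes, ...)
}

#' Analysis chain entered at the spike-train stage
#'
#' @param spikes A `spike_trains` object (e.g. from [detect_spikes()] or
#'   [synth_raster()]).
#' @param ... Burst-detection parameters, see [detect_network_bursts()].
#' @return An `mea_analysis` object, see [analyze_recording()].
#' @export
analyze_spike_trains <- function(spikes, ...) {
  dots <- list(...)
  bursts <- detect_network_bursts(
    spikes,
    bin = dots$bin %||% 0.01, smooth_bins = dots$smooth_bins %||% 3,
    open_frac = dots$open_frac %||% 1 / 4,
    close_frac = dots$close_frac %||% 1 / 100,
    sustain = dots$sustain %||% 0.06, exclusion = dots$exclusion %||% 0.8
  )
  features <- compute_features(spikes, bursts)
  structure(list(spikes = spikes, bursts = bursts, features = features,
                 duration = attr(spikes, "duration"),
                 n_electrodes = attr(spikes, "n_electrodes")),
            class = "mea_analysis")
}

#' Analyze a simulation through the identical MEA chain
#'
#' @param sim An `mea_simulation` from [run_simulation()].
#' @param ... Chain parameters, see [analyze_recording()].
#' @return An `mea_analysis` object.
#' @export
analyze_simulation <- function(sim, ...) {
  analyze_recording(sim$signals, sim$fs, ...)
}

#' @export
print.mea_analysis <- function(x, ...) {
  cat("<mea_analysis>", nrow(x$spikes), "spikes,", nrow(x$bursts),
      "network bursts in", x$duration, "s\n")
  print(x$features)
  invisible(x)
}

#' Synthetic spike raster with known burst epochs
#'
#' Fixture generator for the analysis chain: homogeneous Poisson background
#' per electrode plus synchronized high-rate burst epochs with optional
#' per-electrode timing jitter. The generating epochs are attached as
#' ground truth so detector output can be compared against them.
#'
#' @param duration Recording length (s).
#' @param n_electrodes Number of electrodes.
#' @param background_rate Background rate per electrode (Hz).
#' @param epochs Tibble with columns `start`, `end` (s) and `rate`
#'   (per-electrode rate inside the epoch, Hz); may be `NULL` for
#'   background only.
#' @param jitter SD of a per-electrode time shift applied to epoch spikes
#'   (s).
#' @return A `spike_trains` tibble with a `ground_truth` attribute holding
#'   the epoch table.
#' @export
synth_raster <- function(duration, n_electrodes = 12, background_rate = 0.2,
                         epochs = NULL, jitter = 0.002) {
  stopifnot(duration > 0, n_electrodes >= 1, background_rate >= 0)
  rows <- lapply(seq_len(n_electrodes), function(e) {
    n_bg <- stats::rpois(1, background_rate * duration)
    times <- stats::runif(n_bg, 0, duration)
    if (!is.null(epochs) && nrow(epochs) > 0) {
      for (k in seq_len(nrow(epochs))) {
        len <- epochs$end[k] - epochs$start[k]
        n_ep <- stats::rpois(1, epochs$rate[k] * len)
        et <- stats::runif(n_ep, epochs$start[k], epochs$end[k])
        if (jitter > 0) et <- et + stats::rnorm(1, 0, jitter)
        times <- c(times, et)
      }
    }
    times <- sort(times[times >= 0 & times < duration])
    tibble::tibble(electrode = e, time = times)
  })
  out <- new_spike_trains(dplyr::bind_rows(rows), duration, n_electrodes)
  attr(out, "ground_truth") <- epochs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
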