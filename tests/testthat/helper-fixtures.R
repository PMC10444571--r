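# Shared miniature configurations for engine-level tests: small network,
# short duration, so each simulation runs in well under a second.
tiny_config <- function(seed = 11, duration = 8, transient = 2, N = 20,
                        condition = condition_spec("control"), ...) {
  simulation_config(duration = duration, transient_discard = transient,
                    N = N, seed = seed, condition = condition,
                    n_networks = 2, ...)
}

# deterministic spike raster: every electrode fires a regular train inside
# given windows; returns a spike_trains object
regular_burst_raster <- function(duration, n_electrodes, windows,
                                 rate_in = 200, background = NULL) {
  rows <- lapply(seq_len(n_electrodes), function(e) {
    t <- unlist(lapply(seq_len(nrow(windows)), function(k) {
      seq(windows$start[k], windows$end[k] - 1e-9, by = 1 / rate_in)
    }))
    if (!is.null(background)) t <- c(t, background)
    tibble::tibble(electrode = e, time = sort(t))
  })
  measim:::new_spike_trains(dplyr::bind_rows(rows), duration, n_electrodes)
}
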