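#' Store / load a simulation result
#'
#' Serializes a simulation to a directory: ground-truth spike times as CSV
#' (`spikes.csv`: neuron_id, time_s), the configuration echo (including
#' seed and condition name) as JSON, and the electrode signal matrix as an
#' Arrow Feather table (`signals.feather`, one column per electrode). The
#' round trip is lossless for the spike table and within floating-point
#' precision for the signals.
#'
#' @param sim An `mea_simulation`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_result <- function(sim, path) {
  stopifnot(inherits(sim, "mea_simulation"))
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the arrow package is required for signal serialization",
         call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(neuron_id = sim$spikes$neuron, time_s = sim$spikes$time),
    file.path(path, "spikes.csv"), row.names = FALSE
  )
  sig <- as.data.frame(t(sim$signals))
  names(sig) <- paste0("electrode_", seq_len(nrow(sim$signals)))
  arrow::write_feather(sig, file.path(path, "signals.feather"))
  meta <- list(
    fs = sim$fs, duration = sim$duration, network_id = sim$network_id,
    seed = sim$config$seed, condition = sim$config$condition$name,
    config = config_to_list(sim$config),
    network = list(N = sim$network$N,
                   n_edges = nrow(sim$network$edges))
  )
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$condition <- unclass(out$condition)
  out$condition$modifier <- unclass(out$condition$modifier)
  out$neuron <- unclass(out$neuron)
  out$synapse <- unclass(out$synapse)
  out
}

#' @rdname write_result
#' @param path Directory previously written by [write_result()].
#' @return For `read_result()`: a list with `signals`, `fs`, `spikes`,
#'   `duration`, `meta` (the JSON echo).
#' @export
read_result <- function(path) {
  need <- file.path(path, c("spikes.csv", "signals.feather", "config.json"))
  if (!all(file.exists(need))) {
    stop("missing or corrupt result directory: ", path, call. = FALSE)
  }
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the arrow package is required for signal serialization",
         call. = FALSE)
  }
  spikes_df <- utils::read.csv(need[1])
  sig <- as.matrix(as.data.frame(arrow::read_feather(need[2])))
  meta <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  list(
    signals = t(sig),
    fs = meta$fs,
    spikes = tibble::tibble(neuron = spikes_df$neuron_id,
                            time = spikes_df$time_s),
    duration = meta$duration,
    meta = meta
  )
}
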