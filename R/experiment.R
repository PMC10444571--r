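#' Paired-condition experiment with normalized features
#'
#' Orchestrates the figure-level in-silico experiments: simulates matched
#' baseline + condition pairs ([run_condition_battery()]), normalizes each
#' condition network's features against its matched-seed control
#' (condition / baseline), and summarizes per condition as mean and SEM.
#'
#' @param conditions Condition names or [condition_spec()] list (control is
#'   always included as the baseline).
#' @param config A [simulation_config()].
#' @param n_networks Matched networks per condition.
#' @return An object of class `mea_experiment`: list with `features`
#'   (per-network table), `normalized` (per-network condition/baseline
#'   ratios and deltas), and `summary` (mean, SEM, n per condition and
#'   feature).
#' @export
run_experiment <- function(conditions, config = simulation_config(),
                           n_networks = config$n_networks) {
  tab <- run_condition_battery(conditions, config = config,
                               n_networks = n_networks)
  base <- tab |>
    dplyr::filter(.data$condition == "control") |>
    dplyr::select("network", NBR_ctrl = "NBR", NBD_ctrl = "NBD",
                  PSIB_ctrl = "PSIB", MFR_ctrl = "MFR")
  normalized <- tab |>
    dplyr::filter(.data$condition != "control") |>
    dplyr::left_join(base, by = "network") |>
    dplyr::mutate(
      NBR_norm = .data$NBR / .data$NBR_ctrl,
      NBD_norm = .data$NBD / .data$NBD_ctrl,
      PSIB_norm = .data$PSIB / .data$PSIB_ctrl,
      MFR_delta = .data$MFR - .data$MFR_ctrl
    )
  long <- tab |>
    tidyr::pivot_longer(cols = c("NBR", "NBD", "PSIB", "MFR"),
                        names_to = "feature", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$condition, .data$feature) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = if (sum(!is.na(.data$value)) > 1) {
        stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      } else NA_real_,
      .groups = "drop"
    )
  structure(list(features = tab, normalized = normalized, summary = summary,
                 config = config),
            class = "mea_experiment")
}

#' @export
print.mea_experiment <- function(x, ...) {
  cat("<mea_experiment>", dplyr::n_distinct(x$features$condition),
      "conditions x", dplyr::n_distinct(x$features$network),
      "matched networks\n")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy_measim
#' @export
tidy.mea_experiment <- function(x, ...) x$features

#' @rdname tidy_measim
#' @export
glance.mea_experiment <- function(x, ...) x$summary

#' Tidiers for simulator and analysis objects
#'
#' `tidy()` returns the per-observation table (spike times for analyses and
#' simulations, the per-network feature table for experiments); `glance()`
#' returns the one-row (or per-condition) summary.
#'
#' @param x An `mea_analysis`, `mea_simulation` or `mea_experiment` object.
#' @param ... Unused.
#' @name tidy_measim
NULL

#' @rdname tidy_measim
#' @export
tidy.mea_analysis <- function(x, ...) tibble::as_tibble(x$spikes)

#' @rdname tidy_measim
#' @export
glance.mea_analysis <- function(x, ...) x$features

#' @rdname tidy_measim
#' @export
tidy.mea_simulation <- function(x, ...) x$spikes

#' @rdname tidy_measim
#' @export
glance.mea_simulation <- function(x, ...) {
  glance(analyze_simulation(x))
}
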