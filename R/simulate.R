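# Post-execution simulation pass: given the executed timeline, compute the
# solution actually reaching the chamber, apply the plasticity rule at each
# train, synthesize per-sweep field traces and run the online measurements.

#' Simulate the biology of an executed slice experiment
#'
#' Takes an `experiment_record`, simulates plug-flow transport of the
#' perfused solutions into the chamber, and walks the sweeps in time order:
#' every train sweep (more than one S0 pulse) potentiates the pathway by the
#' slice model's `ltp_factor` -- unless the summed chamber concentration of
#' the inhibitor channels' solutions is at or above `block_threshold` at
#' train onset. Each sweep's field trace is then synthesized at the
#' pathway's current slope and its initial slope measured over the model's
#' slope window, mirroring the online analysis.
#'
#' @param record an `experiment_record` from [run_protocol()].
#' @param rig the [rig_config()] it ran on; must carry a [slice_model()] and
#'   tubing for `line`.
#' @param line the perfusion line feeding the chamber.
#' @param transport_dt_s transport integration step, s.
#' @return a `slice_simulation`: list with `traces` (one [trace()] per
#'   sweep), `measurements` (the spreadsheet data frame: sweep_time_s,
#'   sweep_name, pathway, kind, value), `chamber` (transport series),
#'   `trains` (per-train chamber inhibitor concentration and whether
#'   potentiation occurred), `slope_by_sweep`, and the input `record`.
#' @export
simulate_slice_experiment <- function(record, rig, line = "Slow0",
                                      transport_dt_s = 0.5) {
  slice <- rig$slice
  if (is.null(slice)) stop("rig has no slice model", call. = FALSE)
  sw <- record_switches(record, line)
  chamber <- NULL
  inhibitor_conc <- function(t) 0
  active <- sw[sw$to_channel > 0L, , drop = FALSE]
  if (nrow(active)) {
    tubing <- rig$tubing[[line]]
    if (is.null(tubing)) stop("rig has no tubing for line ", line,
                              call. = FALSE)
    tm <- transport_model(tubing, rig$flow_rate_ml_min, rig$chamber_volume_ml)
    chamber <- advance_transport(tm, sw, dt = transport_dt_s,
                                 t_end = record$end_time_s)
    inh_solutes <- unique(sw$solute[sw$to_channel %in% slice$inhibitor_channels])
    cols <- paste0("chamber_", inh_solutes)
    cols <- cols[cols %in% names(chamber)]
    if (length(cols)) {
      tot <- rowSums(chamber[, cols, drop = FALSE])
      inhibitor_conc <- stats::approxfun(chamber$time_s, tot, rule = 2)
    }
  }

  sweeps <- record$sweeps[order(record$sweeps$start_time_s), , drop = FALSE]
  slope <- slice$baseline_slope
  traces <- vector("list", nrow(sweeps))
  slope_by_sweep <- numeric(nrow(sweeps))
  meas <- vector("list", nrow(sweeps))
  trains <- list()
  for (k in seq_len(nrow(sweeps))) {
    swp <- sweeps[k, ]
    sd <- rig$sweep_defs[[swp$name]]
    is_train <- !is.null(sd$s0_train) && sd$s0_train$pulse_count > 1L
    seed_k <- if (is.null(slice$rng_seed)) NULL else slice$rng_seed + swp$index
    tr <- synth_field_sweep(slice, sd, slope = slope, seed = seed_k)
    traces[[swp$index]] <- tr
    slope_by_sweep[k] <- slope
    onset <- sd$s0_train$onset_ms
    win <- onset + slice$slope_window_ms
    meas[[k]] <- data.frame(sweep_time_s = swp$start_time_s,
                            sweep_name = swp$name, pathway = "S0",
                            kind = "slope",
                            value = measure_slope(tr, win),
                            stringsAsFactors = FALSE)
    if (is_train) {
      conc <- inhibitor_conc(swp$start_time_s)
      potentiated <- conc < slice$block_threshold
      if (potentiated) slope <- slope * slice$ltp_factor
      trains[[length(trains) + 1L]] <-
        data.frame(time_s = swp$start_time_s, sweep_name = swp$name,
                   inhibitor_conc = conc, potentiated = potentiated)
    }
  }
  structure(list(
    record = record,
    traces = traces,
    measurements = if (length(meas)) do.call(rbind, meas) else NULL,
    chamber = chamber,
    trains = if (length(trains)) do.call(rbind, trains) else NULL,
    slope_by_sweep = data.frame(index = sweeps$index,
                                start_time_s = sweeps$start_time_s,
                                name = sweeps$name, slope = slope_by_sweep),
    final_slope = slope), class = "slice_simulation")
}

#' @export
print.slice_simulation <- function(x, ...) {
  cat(sprintf("<slice_simulation> %d sweep(s), %d train(s); final slope %.3g mV/ms\n",
              length(x$traces), if (is.null(x$trains)) 0L else nrow(x$trains),
              x$final_slope))
  if (!is.null(x$trains)) print.data.frame(x$trains)
  invisible(x)
}

#' Mean measured slope before the first train and after the last
#'
#' The standard LTP summary: the ratio of the post-induction to baseline
#' fEPSP slope.
#'
#' @param sim a `slice_simulation`.
#' @param n_baseline use the last `n_baseline` pre-train sweeps.
#' @param n_post use the last `n_post` sweeps of the experiment.
#' @return list with `pre`, `post` (mean measured slopes) and `ratio`
#'   (post/pre).
#' @export
ltp_summary <- function(sim, n_baseline = 3, n_post = 3) {
  m <- sim$measurements
  m <- m[m$kind == "slope", , drop = FALSE]
  if (is.null(sim$trains) || nrow(sim$trains) == 0L)
    stop("no train sweeps in this simulation", call. = FALSE)
  t_first <- min(sim$trains$time_s)
  t_last <- max(sim$trains$time_s)
  pre <- m[m$sweep_time_s < t_first & m$sweep_name %in% c("P0sweep", "P1sweep"), ]
  post <- m[m$sweep_time_s > t_last & m$sweep_name %in% c("P0sweep", "P1sweep"), ]
  pre_v <- utils::tail(pre$value, n_baseline)
  post_v <- utils::tail(post$value, n_post)
  list(pre = mean(pre_v), post = mean(post_v),
       ratio = mean(post_v) / mean(pre_v))
}

#' Write an executed experiment to a directory of text outputs
#'
#' Produces `experiment.log` (the experimental log), `timeline.csv` (merged
#' valve actions), `sweeps.csv`, `continuous.csv` (gap-free commanded
#' channel of `line`), and, when a simulation is given, `spreadsheet.csv`
#' (per-sweep measurements) and per-sweep trace CSVs under `sweep_<n>.csv`.
#'
#' @param record an `experiment_record`.
#' @param dir output directory (created if missing).
#' @param rig the rig the record ran on (for the continuous trace).
#' @param sim optional `slice_simulation`.
#' @param line line for the continuous trace.
#' @return `dir`, invisibly.
#' @export
write_experiment_dir <- function(record, dir, rig = NULL, sim = NULL,
                                 line = "Slow0") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(emit_log(record), file.path(dir, "experiment.log"))
  utils::write.csv(record$valve_timeline, file.path(dir, "timeline.csv"),
                   row.names = FALSE)
  utils::write.csv(record$sweeps, file.path(dir, "sweeps.csv"),
                   row.names = FALSE)
  if (!is.null(rig))
    utils::write.csv(continuous_channel_trace(record, rig, line),
                     file.path(dir, "continuous.csv"), row.names = FALSE)
  if (!is.null(sim)) {
    utils::write.csv(sim$measurements, file.path(dir, "spreadsheet.csv"),
                     row.names = FALSE)
    for (i in seq_along(sim$traces)) {
      if (!is.null(sim$traces[[i]]))
        trace_to_csv(sim$traces[[i]], file.path(dir, sprintf("sweep_%03d.csv", i)))
    }
  }
  invisible(dir)
}
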