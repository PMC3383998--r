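# Sweep definitions and waveform rendering: stimulus pulse trains on the
# digital S0/S1 outputs, command steps on IC0, and within-sweep perfusion
# epochs on IC1.

#' Define a pulse train for a digital stimulator trigger output
#'
#' @param onset_ms time of the first pulse's rising edge within the sweep.
#' @param pulse_count number of pulses.
#' @param interval_ms inter-pulse interval (rising edge to rising edge).
#' @param pulse_width_ms width of each pulse.
#' @return a `pulse_train` list.
#' @export
pulse_train <- function(onset_ms, pulse_count, interval_ms = 10,
                        pulse_width_ms = 0.1) {
  stopifnot(onset_ms >= 0, pulse_count >= 1, pulse_width_ms > 0,
            pulse_count == 1 || interval_ms > 0)
  structure(list(onset_ms = onset_ms, pulse_count = as.integer(pulse_count),
                 interval_ms = interval_ms, pulse_width_ms = pulse_width_ms),
            class = "pulse_train")
}

#' Define a stimulation/acquisition sweep
#'
#' A sweep is one timed stimulation + acquisition episode. Protocols use four
#' named sweeps: single-pulse `P0sweep`/`P1sweep` and train `T0sweep`/
#' `T1sweep`. A sweep renders to sampled outputs: digital stimulator triggers
#' `S0`/`S1`, the patch command output `IC0`, and the perfusion command
#' output `IC1`, which is divided into exactly three epochs (Step0/1/2).
#' An epoch amplitude of -1 is a sentinel meaning "hold whatever channel the
#' fast perfusion line is currently set to"; other amplitudes select a
#' perfusion channel for the duration of the epoch.
#'
#' @param name one of `"P0sweep"`, `"P1sweep"`, `"T0sweep"`, `"T1sweep"`.
#' @param duration_ms sweep duration.
#' @param sample_rate_hz sampling rate of the rendered waveforms (default
#'   10 kHz; pulse edges are scheduled at exact times and then quantized to
#'   the sample grid, so edge placement carries no cumulative drift).
#' @param s0_train,s1_train optional [pulse_train()]s.
#' @param ic0_steps optional data frame of command steps with columns
#'   `onset_ms`, `duration_ms`, `amplitude_V`.
#' @param ic1_epochs data frame of exactly 3 rows with columns `duration_ms`
#'   and `amplitude` (channel units, or -1 sentinel), or `NULL` for no
#'   within-sweep perfusion control.
#' @return an object of class `sweep_def`.
#' @export
sweep_def <- function(name = c("P0sweep", "P1sweep", "T0sweep", "T1sweep"),
                      duration_ms = 200, sample_rate_hz = 10000,
                      s0_train = NULL, s1_train = NULL,
                      ic0_steps = NULL, ic1_epochs = NULL) {
  name <- match.arg(name)
  stopifnot(duration_ms > 0, sample_rate_hz > 0)
  for (tr in list(s0_train, s1_train)) {
    if (!is.null(tr)) {
      stopifnot(inherits(tr, "pulse_train"))
      t_end <- tr$onset_ms + (tr$pulse_count - 1L) * tr$interval_ms +
        tr$pulse_width_ms
      if (t_end > duration_ms)
        stop("pulse train (ends at ", t_end, " ms) exceeds sweep duration (",
             duration_ms, " ms)", call. = FALSE)
    }
  }
  if (!is.null(ic1_epochs)) {
    stopifnot(is.data.frame(ic1_epochs), nrow(ic1_epochs) == 3L,
              all(c("duration_ms", "amplitude") %in% names(ic1_epochs)))
    if (sum(ic1_epochs$duration_ms) > duration_ms + 1e-9)
      stop("IC1 epoch durations exceed sweep duration", call. = FALSE)
  }
  structure(list(name = name, duration_ms = duration_ms,
                 sample_rate_hz = sample_rate_hz,
                 s0_train = s0_train, s1_train = s1_train,
                 ic0_steps = ic0_steps, ic1_epochs = ic1_epochs),
            class = "sweep_def")
}

#' @export
print.sweep_def <- function(x, ...) {
  cat(sprintf("<sweep_def> %s: %g ms @ %g kHz", x$name, x$duration_ms,
              x$sample_rate_hz / 1000))
  if (!is.null(x$s0_train))
    cat(sprintf("; S0 %d pulse(s)", x$s0_train$pulse_count))
  if (!is.null(x$s1_train))
    cat(sprintf("; S1 %d pulse(s)", x$s1_train$pulse_count))
  if (!is.null(x$ic1_epochs))
    cat(sprintf("; IC1 epochs [%s]",
                paste(x$ic1_epochs$amplitude, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Resolve a sweep-epoch amplitude to an output voltage
#'
#' The sentinel amplitude -1 holds the channel most recently set by a fast
#' Perfuse event between sweeps. Any other amplitude selects a channel: in
#' `"channel"` units mode one amplitude unit is one channel (converted via
#' the controller's volts/channel at the output); in `"volts"` mode the
#' amplitude is taken as literal volts and must land on a valid channel.
#'
#' @param amplitude epoch amplitude (channel units or -1 sentinel).
#' @param current_channel the line's current channel (used by the sentinel).
#' @param cfg the fast line's [controller_config()].
#' @return output voltage.
#' @export
resolve_epoch_voltage <- function(amplitude, current_channel, cfg) {
  if (identical(as.numeric(amplitude), -1)) {
    return(encode_analog(current_channel, cfg))
  }
  ch <- if (cfg$amplitude_units == "channel") amplitude
        else amplitude / cfg$volts_per_channel
  if (abs(ch - round(ch)) > 1e-9 || round(ch) < 0 || round(ch) > cfg$n_channels)
    stop("epoch amplitude ", amplitude, " selects no valid channel on a ",
         cfg$n_channels, "-channel controller", call. = FALSE)
  encode_analog(as.integer(round(ch)), cfg)
}

#' Epoch channel number implied by an amplitude (sentinel-aware)
#' @inheritParams resolve_epoch_voltage
#' @return integer channel.
#' @export
resolve_epoch_channel <- function(amplitude, current_channel, cfg) {
  if (identical(as.numeric(amplitude), -1)) return(as.integer(current_channel))
  as.integer(round(resolve_epoch_voltage(amplitude, current_channel, cfg) /
                     cfg$volts_per_channel))
}

#' Render a sweep definition to sampled output waveforms
#'
#' Produces the digital S0/S1 series, the IC0 command series and the IC1
#' perfusion-command series, all sampled at the sweep's rate. Sample i
#' covers time `[i, i+1) / rate`; an output is high at sample i if the
#' scheduled event spans that sample's start time, so the k-th pulse edge
#' lands at `onset + k * interval` exactly with no cumulative rounding.
#'
#' @param sweep a [sweep_def()].
#' @param state named list of current channels per fast line, e.g.
#'   `list(Fast0 = 1)`; used to resolve -1 sentinel epochs.
#' @param cfg the [controller_config()] of the line driven by IC1 (used to
#'   convert epoch amplitudes to volts); may be `NULL` when the sweep has no
#'   IC1 epochs.
#' @return an object of class `sweep_waveforms`: list with `t_ms`, `S0`,
#'   `S1`, `IC0_V`, `IC1_V` (equal-length vectors), the rendered epoch table
#'   `ic1_resolved` (onset, duration, channel, volts), and edge times.
#' @export
render_sweep <- function(sweep, state = list(), cfg = NULL) {
  stopifnot(inherits(sweep, "sweep_def"))
  rate <- sweep$sample_rate_hz
  n <- as.integer(round(sweep$duration_ms * rate / 1000))
  t_ms <- (seq_len(n) - 1L) / rate * 1000

  render_train <- function(tr) {
    y <- integer(n)
    edges <- numeric(0)
    if (!is.null(tr)) {
      edges <- tr$onset_ms + (seq_len(tr$pulse_count) - 1L) * tr$interval_ms
      for (e in edges) {
        i0 <- ceiling(e * rate / 1000 - 1e-9) + 1L
        i1 <- ceiling((e + tr$pulse_width_ms) * rate / 1000 - 1e-9)
        i1 <- max(i1, i0)  # sub-sample pulses still occupy one sample
        y[i0:min(i1, n)] <- 1L
      }
    }
    list(y = y, edges = edges)
  }
  s0 <- render_train(sweep$s0_train)
  s1 <- render_train(sweep$s1_train)

  ic0 <- numeric(n)
  if (!is.null(sweep$ic0_steps)) {
    for (i in seq_len(nrow(sweep$ic0_steps))) {
      st <- sweep$ic0_steps[i, ]
      sel <- t_ms >= st$onset_ms - 1e-9 &
        t_ms < st$onset_ms + st$duration_ms - 1e-9
      ic0[sel] <- st$amplitude_V
    }
  }

  ic1 <- numeric(n)
  ic1_resolved <- NULL
  if (!is.null(sweep$ic1_epochs)) {
    if (is.null(cfg))
      stop("sweep has IC1 epochs but no fast-line controller config given",
           call. = FALSE)
    cur <- state[[cfg$line]]
    if (is.null(cur)) cur <- 0L
    onset <- 0
    rows <- vector("list", 3L)
    for (i in 1:3) {
      ep <- sweep$ic1_epochs[i, ]
      v <- resolve_epoch_voltage(ep$amplitude, cur, cfg)
      ch <- resolve_epoch_channel(ep$amplitude, cur, cfg)
      sel <- t_ms >= onset - 1e-9 & t_ms < onset + ep$duration_ms - 1e-9
      ic1[sel] <- v
      rows[[i]] <- data.frame(epoch = i - 1L, onset_ms = onset,
                              duration_ms = ep$duration_ms,
                              sentinel = identical(as.numeric(ep$amplitude), -1),
                              channel = ch, volts = v)
      onset <- onset + ep$duration_ms
    }
    ic1_resolved <- do.call(rbind, rows)
    # after the declared epochs the output holds the last epoch's level
    if (onset < sweep$duration_ms) ic1[t_ms >= onset - 1e-9] <- ic1_resolved$volts[3]
  }

  structure(list(t_ms = t_ms, S0 = s0$y, S1 = s1$y, IC0_V = ic0, IC1_V = ic1,
                 s0_edges_ms = s0$edges, s1_edges_ms = s1$edges,
                 ic1_resolved = ic1_resolved,
                 name = sweep$name, duration_ms = sweep$duration_ms,
                 sample_rate_hz = rate),
            class = "sweep_waveforms")
}

#' @export
print.sweep_waveforms <- function(x, ...) {
  cat(sprintf("<sweep_waveforms> %s: %d samples @ %g kHz; %d S0 / %d S1 pulses\n",
              x$name, length(x$t_ms), x$sample_rate_hz / 1000,
              count_pulses(x, "S0"), count_pulses(x, "S1")))
  invisible(x)
}

#' Count stimulus pulses on a rendered digital output
#'
#' @param w a `sweep_waveforms` object from [render_sweep()].
#' @param output `"S0"` or `"S1"`.
#' @return number of 0 -> 1 transitions.
#' @export
count_pulses <- function(w, output = c("S0", "S1")) {
  output <- match.arg(output)
  y <- w[[output]]
  sum(diff(c(0L, y)) == 1L)
}

#' Export rendered waveforms as a data frame / CSV
#'
#' @param w a `sweep_waveforms`.
#' @param path optional file path; when given, written as CSV.
#' @return data frame with columns time_ms, S0, S1, IC0_V, IC1_V (invisibly
#'   when written to file).
#' @export
waveforms_to_csv <- function(w, path = NULL) {
  df <- data.frame(time_ms = w$t_ms, S0 = w$S0, S1 = w$S1,
                   IC0_V = w$IC0_V, IC1_V = w$IC1_V)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
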