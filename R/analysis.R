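# Online per-sweep measurement battery: slope, maximum slope, peak
# amplitude, population-spike amplitude, average amplitude, area, rise time,
# decay time, duration, input resistance and series resistance.
#
# The definitions follow standard electrophysiology practice: OLS slope,
# 10-90% rise time, peak-to-37% decay time, full width at half maximum,
# chord-referenced population spike, and back-extrapolated series
# resistance; all windows/conventions are arguments.

#' A uniformly sampled acquisition trace
#'
#' @param samples numeric vector (mV or pA).
#' @param dt_ms sample interval.
#' @param t0_ms time of the first sample.
#' @param units unit string, carried along for labeling.
#' @return an object of class `trace`.
#' @export
trace <- function(samples, dt_ms, t0_ms = 0, units = "mV") {
  stopifnot(is.numeric(samples), length(samples) >= 2L, dt_ms > 0)
  structure(list(samples = as.numeric(samples), dt_ms = dt_ms, t0_ms = t0_ms,
                 units = units), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g kHz, %g-%g ms, %s\n",
              length(x$samples), 1 / x$dt_ms, x$t0_ms,
              x$t0_ms + (length(x$samples) - 1L) * x$dt_ms, x$units))
  invisible(x)
}

trace_times <- function(tr) tr$t0_ms + (seq_along(tr$samples) - 1L) * tr$dt_ms

window_idx <- function(tr, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  t <- trace_times(tr)
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(idx) == 0L)
    stop("window [", window[1], ", ", window[2], "] ms lies outside the trace",
         call. = FALSE)
  idx
}

#' Write a trace as CSV (time_ms, value)
#' @param tr a [trace()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
trace_to_csv <- function(tr, path) {
  utils::write.csv(data.frame(time_ms = trace_times(tr), value = tr$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Measurement specification
#'
#' @param kind one of `"slope"`, `"max_slope"`, `"peak_amplitude"`,
#'   `"pop_spike"`, `"average_amplitude"`, `"area"`, `"rise_time"`,
#'   `"decay_time"`, `"duration"`, `"input_resistance"`,
#'   `"series_resistance"`.
#' @param window `(t1_ms, t2_ms)` analysis window.
#' @param baseline_window window whose mean defines the baseline (for
#'   peak-relative kinds).
#' @param options kind-specific options (e.g. `subwindow_ms` for max_slope,
#'   `n_exp` for series resistance, `decay_fraction`).
#' @return an object of class `measurement_spec`.
#' @export
measurement_spec <- function(kind, window, baseline_window = NULL,
                             options = list()) {
  kind <- match.arg(kind, c("slope", "max_slope", "peak_amplitude",
                            "pop_spike", "average_amplitude", "area",
                            "rise_time", "decay_time", "duration",
                            "input_resistance", "series_resistance"))
  structure(list(kind = kind, window = window,
                 baseline_window = baseline_window, options = options),
            class = "measurement_spec")
}

#' Ordinary least-squares slope of a trace over a window
#'
#' @param tr a [trace()].
#' @param window `(t1_ms, t2_ms)`; must contain at least 3 samples.
#' @return slope in trace-units per ms.
#' @export
measure_slope <- function(tr, window) {
  idx <- window_idx(tr, window)
  if (length(idx) < 3L)
    stop("slope window must contain at least 3 samples", call. = FALSE)
  t <- trace_times(tr)[idx]
  y <- tr$samples[idx]
  unname(stats::cov(t, y) / stats::var(t))
}

#' Maximum sliding-window slope
#'
#' The maximum over OLS slopes of all subwindows of width `subwindow_ms`
#' sliding through `window` at 1-sample stride.
#'
#' @param tr a [trace()].
#' @param window outer window `(t1_ms, t2_ms)`.
#' @param subwindow_ms sliding-window width (must span >= 3 samples and be
#'   smaller than the outer window).
#' @return maximum slope, trace-units per ms.
#' @export
measure_max_slope <- function(tr, window, subwindow_ms) {
  idx <- window_idx(tr, window)
  m <- as.integer(round(subwindow_ms / tr$dt_ms)) + 1L  # samples per subwindow
  if (m < 3L) stop("subwindow too small: fewer than 3 samples", call. = FALSE)
  if (m > length(idx))
    stop("subwindow exceeds the analysis window", call. = FALSE)
  t <- trace_times(tr)[idx]
  y <- tr$samples[idx]
  n <- length(idx)
  # rolling sums via cumulative sums: slope = (m Sxy - Sx Sy)/(m Sxx - Sx^2)
  cs <- function(v) c(0, cumsum(v))
  roll <- function(v) {
    c0 <- cs(v)
    c0[(m + 1L):(n + 1L)] - c0[1L:(n - m + 1L)]
  }
  sx <- roll(t); sy <- roll(y); sxx <- roll(t * t); sxy <- roll(t * y)
  max((m * sxy - sx * sy) / (m * sxx - sx^2))
}

baseline_mean <- function(tr, baseline_window) {
  if (is.null(baseline_window)) return(0)
  mean(tr$samples[window_idx(tr, baseline_window)])
}

# linear-interpolated crossing times of |deviation| through `level`,
# restricted to the given index range; direction +1 = upward crossing.
crossings <- function(t, d, level, direction = 1) {
  s <- direction * (d - level)
  k <- which(s[-length(s)] < 0 & s[-1L] >= 0)
  if (length(k) == 0L) return(numeric(0))
  t[k] + (t[k + 1L] - t[k]) * (-s[k]) / (s[k + 1L] - s[k])
}

#' Peak-relative waveform measurements
#'
#' Computes one of the standard per-sweep measurements, all relative to the
#' mean of `baseline_window`:
#' \describe{
#'   \item{peak_amplitude}{signed extreme deviation from baseline.}
#'   \item{average_amplitude}{mean deviation over the window.}
#'   \item{area}{trapezoidal integral of the deviation (units x ms).}
#'   \item{rise_time}{time from 10% to 90% of peak on the rising phase.}
#'   \item{decay_time}{time from the peak to `decay_fraction` (default 37%)
#'     of peak on the falling phase.}
#'   \item{duration}{full width at half of the peak deviation.}
#'   \item{pop_spike}{vertical distance from the negative spike trough to
#'     the chord joining the two flanking positive peaks.}
#' }
#'
#' @param tr a [trace()].
#' @param kind measurement kind (see above) or a [measurement_spec()].
#' @param window analysis window `(t1_ms, t2_ms)`.
#' @param baseline_window baseline window; `NULL` means baseline 0.
#' @param decay_fraction fraction of peak defining decay time (0.37
#'   approximates one exponential time constant).
#' @return the measurement value (ms for the time kinds).
#' @export
measure_basic <- function(tr, kind, window = NULL, baseline_window = NULL,
                          decay_fraction = 0.37) {
  if (inherits(kind, "measurement_spec")) {
    spec <- kind
    kind <- spec$kind
    window <- spec$window
    baseline_window <- spec$baseline_window
    decay_fraction <- spec$options$decay_fraction %||% decay_fraction
  }
  kind <- match.arg(kind, c("peak_amplitude", "average_amplitude", "area",
                            "rise_time", "decay_time", "duration",
                            "pop_spike"))
  idx <- window_idx(tr, window)
  t <- trace_times(tr)[idx]
  d <- tr$samples[idx] - baseline_mean(tr, baseline_window)

  if (kind == "average_amplitude") return(mean(d))
  if (kind == "area") return(pracma::trapz(t, d))

  ipk <- which.max(abs(d))
  peak <- d[ipk]
  if (kind == "peak_amplitude") return(peak)

  if (kind == "pop_spike") {
    itr <- which.min(d)
    if (itr <= 1L || itr >= length(d))
      stop("no interior trough found for pop-spike measurement", call. = FALSE)
    i1 <- which.max(d[1:(itr - 1L)])
    i2 <- itr + which.max(d[(itr + 1L):length(d)])
    chord <- d[i1] + (d[i2] - d[i1]) * (t[itr] - t[i1]) / (t[i2] - t[i1])
    return(chord - d[itr])
  }

  if (abs(peak) < .Machine$double.eps^0.5)
    stop("flat trace: no identifiable peak for ", kind, call. = FALSE)
  # work on the peak-signed deviation so "rising" always means toward peak
  u <- d * sign(peak)
  apk <- abs(peak)

  if (kind == "rise_time") {
    t10 <- crossings(t[1:ipk], u[1:ipk], 0.10 * apk)
    t90 <- crossings(t[1:ipk], u[1:ipk], 0.90 * apk)
    if (length(t10) == 0L || length(t90) == 0L)
      stop("rise time undefined: no 10%/90% crossings before the peak",
           call. = FALSE)
    return(max(t90) - max(t10[t10 <= max(t90)]))
  }
  if (kind == "decay_time") {
    seg <- ipk:length(u)
    tc <- crossings(t[seg], u[seg], decay_fraction * apk, direction = -1)
    if (length(tc) == 0L)
      stop("decay time undefined: trace does not fall to ",
           decay_fraction * 100, "% of peak", call. = FALSE)
    return(tc[1L] - t[ipk])
  }
  # duration: full width at half maximum
  half <- 0.5 * apk
  up <- crossings(t, u, half, direction = 1)
  down <- crossings(t, u, half, direction = -1)
  if (length(up) == 0L && u[1L] >= half) up <- t[1L]
  if (length(down) == 0L && u[length(u)] >= half) down <- t[length(u)]
  if (length(up) == 0L || length(down) == 0L)
    stop("duration undefined: no half-peak crossings", call. = FALSE)
  max(down) - min(up)
}

#' Input resistance from a test step
#'
#' Ohm's law on the steady-state deflection: the baseline-subtracted mean
#' over the late `window` divided by the step. With a voltage trace (mV) and
#' a current step (pA), or a current trace (pA) and a voltage step (mV), the
#' result is in megohms.
#'
#' @param tr a [trace()].
#' @param step_pA injected current step (for current-clamp voltage traces).
#' @param step_mV command voltage step (for voltage-clamp current traces).
#' @param window steady-state window `(t1_ms, t2_ms)`.
#' @param baseline_window pre-step baseline window.
#' @return resistance in MOhm.
#' @export
input_resistance <- function(tr, step_pA = NULL, step_mV = NULL,
                             window, baseline_window = NULL) {
  dv <- mean(tr$samples[window_idx(tr, window)]) -
    baseline_mean(tr, baseline_window)
  if (!is.null(step_pA)) {
    if (step_pA == 0) stop("zero step", call. = FALSE)
    return(1000 * dv / step_pA)             # mV / pA -> MOhm
  }
  if (is.null(step_mV) || step_mV == 0) stop("zero step", call. = FALSE)
  if (abs(dv) < .Machine$double.eps) return(Inf)
  1000 * step_mV / dv                        # mV / pA -> MOhm
}

#' Series resistance by exponential fit of the seal-test transient
#'
#' Fits `I(t) = I_ss + sum_i A_i exp(-(t - t_peak)/tau_i)` (1 or 2
#' components) from the transient peak onward by nonlinear least squares
#' (Levenberg-Marquardt), seeded from a log-linear fit of the tail. The peak
#' current is back-extrapolated to the transient onset as
#' `I_peak = I_ss + sum A_i`, and `Rs = step / I_peak`.
#'
#' @param tr a [trace()] of the current transient, pA.
#' @param step_mV the voltage-step amplitude.
#' @param n_exp 1 or 2 exponential components.
#' @return list with `Rs_MOhm`, `tau_ms` (length `n_exp`), `I_peak_pA`,
#'   `I_ss_pA`, `residual` (RMS of fit residuals) and the `nls` fit object.
#' @export
series_resistance_fit <- function(tr, step_mV, n_exp = 1) {
  stopifnot(n_exp %in% c(1L, 2L), step_mV != 0)
  y <- tr$samples
  t <- trace_times(tr)
  i_ss0 <- mean(y[max(1L, floor(0.9 * length(y))):length(y)])
  dev <- y - i_ss0
  ipk <- which.max(abs(dev))
  noise_floor <- stats::sd(utils::tail(dev, max(10L, length(y) %/% 10L)))
  if (abs(dev[ipk]) < max(4 * noise_floor, .Machine$double.eps^0.25))
    stop("flat transient: no capacitive peak above the noise floor",
         call. = FALSE)
  ts <- t[ipk:length(t)] - t[ipk]
  ys <- y[ipk:length(y)]
  window_ms <- ts[length(ts)]

  # log-linear starting values from the early decay
  pos <- sign(dev[ipk])
  dec <- pos * (ys - i_ss0)
  ok <- which(dec > max(dec) * 0.02)
  ok <- ok[ok <= max(which(dec > max(dec) * 0.2), 10L)]
  lf <- stats::lm(log(dec[ok]) ~ ts[ok])
  tau0 <- max(-1 / stats::coef(lf)[2L], 0.02)
  a0 <- pos * exp(stats::coef(lf)[1L])

  lower_tau <- 0.01
  upper_tau <- 10 * window_ms
  fit <- if (n_exp == 1L) {
    minpack.lm::nlsLM(
      ys ~ c0 + a1 * exp(-ts / tau1),
      start = list(c0 = i_ss0, a1 = a0, tau1 = tau0),
      lower = c(-Inf, -Inf, lower_tau), upper = c(Inf, Inf, upper_tau),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      ys ~ c0 + a1 * exp(-ts / tau1) + a2 * exp(-ts / tau2),
      start = list(c0 = i_ss0, a1 = a0 * 0.7, tau1 = tau0 * 0.5,
                   a2 = a0 * 0.3, tau2 = tau0 * 3),
      lower = c(-Inf, -Inf, lower_tau, -Inf, lower_tau),
      upper = c(Inf, Inf, upper_tau, Inf, upper_tau),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  amps <- cf[grep("^a", names(cf))]
  taus <- sort(unname(cf[grep("^tau", names(cf))]))
  i_peak <- unname(cf["c0"] + sum(amps))
  res <- sqrt(mean(stats::resid(fit)^2))
  if (!is.finite(i_peak) || abs(i_peak) < .Machine$double.eps)
    stop("series-resistance fit did not converge (residual ", signif(res, 3),
         ")", call. = FALSE)
  list(Rs_MOhm = 1000 * step_mV / i_peak, tau_ms = taus,
       I_peak_pA = i_peak, I_ss_pA = unname(cf["c0"]),
       residual = res, fit = fit)
}
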