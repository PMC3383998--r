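# The virtual rig: plug-flow solution transport with stale-solution
# tracking, and parameterized synthesis of field-EPSP, agonist-response and
# seal-test traces. These are the simplest fully-parameterized stand-ins
# that make every executor and analysis path exercisable; they model no
# receptor kinetics, temperature effects or electrode drift.

# Run expr under a local, restorable RNG state (NULL seed = use current RNG).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# ---- models -----------------------------------------------------------------

#' Virtual slice (field-potential) model
#'
#' A pathway with a baseline fEPSP initial slope that potentiates by a fixed
#' factor when a train sweep is delivered -- unless the chamber concentration
#' of an inhibitor solution is at or above a blocking threshold at train
#' time, in which case the train has no lasting effect.
#'
#' @param baseline_slope baseline fEPSP initial slope in mV/ms (negative:
#'   the synaptic deflection is negative-going).
#' @param ltp_factor multiplicative potentiation per effective train (>= 1).
#' @param inhibitor_channels channel number(s) whose solution blocks
#'   induction.
#' @param block_threshold chamber concentration fraction (0-1) at or above
#'   which induction is blocked.
#' @param noise_sd additive Gaussian trace noise, mV.
#' @param slope_window_ms measurement window relative to each stimulus pulse
#'   within which the synthetic waveform's initial slope is calibrated.
#' @param rng_seed seed for trace noise (NULL = use the session RNG).
#' @return an object of class `slice_model`.
#' @export
slice_model <- function(baseline_slope = -0.15, ltp_factor = 1.5,
                        inhibitor_channels = 2L, block_threshold = 0.5,
                        noise_sd = 0.01, slope_window_ms = c(1, 3),
                        rng_seed = NULL) {
  stopifnot(ltp_factor >= 1, block_threshold >= 0, block_threshold <= 1,
            noise_sd >= 0, length(slope_window_ms) == 2L,
            slope_window_ms[1] < slope_window_ms[2])
  structure(list(baseline_slope = baseline_slope, ltp_factor = ltp_factor,
                 inhibitor_channels = as.integer(inhibitor_channels),
                 block_threshold = block_threshold, noise_sd = noise_sd,
                 slope_window_ms = slope_window_ms, rng_seed = rng_seed),
            class = "slice_model")
}

#' Virtual patch-clamp cell model
#'
#' Hill-type agonist concentration-response with competitive (Schild-shift)
#' antagonism, first-order on/off relaxation kinetics, and passive membrane
#' properties for seal-test synthesis.
#'
#' @param Emax maximal agonist-evoked current, pA.
#' @param EC50 agonist half-maximal concentration (same units as the
#'   concentration series passed to [synth_patch_sweep()]).
#' @param hill_h Hill coefficient.
#' @param Ki antagonist equilibrium constant (same units as the antagonist
#'   series).
#' @param tau_on_ms,tau_off_ms activation / deactivation time constants.
#' @param Rin_MOhm input (membrane) resistance.
#' @param Rs_MOhm patch-electrode series (access) resistance.
#' @param Cm_pF membrane capacitance.
#' @param rs_second optional second exponential component of the seal-test
#'   transient: list(frac = amplitude fraction, tau_ms = time constant).
#' @param noise_sd additive Gaussian trace noise, pA.
#' @param rng_seed seed for trace noise (NULL = use the session RNG).
#' @return an object of class `patch_model`.
#' @export
patch_model <- function(Emax = 500, EC50 = 10, hill_h = 1.5, Ki = 5,
                        tau_on_ms = 50, tau_off_ms = 100,
                        Rin_MOhm = 150, Rs_MOhm = 10, Cm_pF = 30,
                        rs_second = NULL, noise_sd = 2, rng_seed = NULL) {
  stopifnot(Emax > 0, EC50 > 0, hill_h > 0, Ki > 0, tau_on_ms > 0,
            tau_off_ms > 0, Rin_MOhm > 0, Rs_MOhm >= 0, Cm_pF > 0,
            noise_sd >= 0)
  if (!is.null(rs_second))
    stopifnot(rs_second$frac > 0, rs_second$frac < 1, rs_second$tau_ms > 0)
  structure(list(Emax = Emax, EC50 = EC50, hill_h = hill_h, Ki = Ki,
                 tau_on_ms = tau_on_ms, tau_off_ms = tau_off_ms,
                 Rin_MOhm = Rin_MOhm, Rs_MOhm = Rs_MOhm, Cm_pF = Cm_pF,
                 rs_second = rs_second, noise_sd = noise_sd,
                 rng_seed = rng_seed),
            class = "patch_model")
}

# ---- plug-flow transport ----------------------------------------------------

#' Plug-flow transport model for one perfusion line
#'
#' The line is a train of tubing segments; solution moves as plugs (no axial
#' mixing), so a plug of volume V arrives at the chamber over V/Q at flow Q.
#' On a channel switch the newly opened line delivers a stale bolus first:
#' under standard switching everything from the reservoir to the manifold is
#' stale, under pre-flush or continuous-flow-to-waste switching only the
#' junction-to-manifold volume is. The chamber is a well-mixed compartment
#' with turnover Q / chamber volume.
#'
#' @param tubing list of [tubing_segment()]s describing the line.
#' @param flow_rate_ml_min flow rate Q.
#' @param chamber_volume_ml chamber volume.
#' @return an object of class `transport_model` with the per-role volumes
#'   precomputed.
#' @export
transport_model <- function(tubing, flow_rate_ml_min = 2,
                            chamber_volume_ml = 1) {
  stopifnot(flow_rate_ml_min > 0, chamber_volume_ml > 0,
            all(vapply(tubing, inherits, TRUE, "tubing_segment")))
  vol_of <- function(role) {
    segs <- Filter(function(s) s$role == role, tubing)
    sum(vapply(segs, dead_volume, 0))
  }
  structure(list(
    tubing = tubing,
    v_reservoir_junction = vol_of("reservoir_to_junction"),
    v_junction_manifold = vol_of("junction_to_manifold"),
    v_manifold_chamber = vol_of("manifold_to_chamber"),
    flow_rate_ml_min = flow_rate_ml_min,
    chamber_volume_ml = chamber_volume_ml), class = "transport_model")
}

#' Stale bolus volume delivered by a switch, by scheme
#'
#' @param model a [transport_model()].
#' @param scheme `"standard"` (reservoir-to-manifold volume is stale),
#'   `"preflush"` or `"flow_to_waste"` (junction-to-manifold only).
#' @return volume in ml.
#' @export
stale_bolus_volume <- function(model,
                               scheme = c("standard", "preflush",
                                          "flow_to_waste")) {
  scheme <- match.arg(scheme)
  if (scheme == "standard")
    model$v_reservoir_junction + model$v_junction_manifold
  else model$v_junction_manifold
}

#' Advance plug-flow transport over a switching timeline
#'
#' Simulates the solution actually reaching the chamber, given the channel
#' switches executed on one line. Each switch injects (behind whatever is
#' already in the line downstream of the valve) a stale plug of the scheme's
#' dead volume, followed by fresh solution of the new channel. The returned
#' series gives the solute composition entering the chamber and the
#' well-mixed chamber concentrations.
#'
#' @param model a [transport_model()].
#' @param switches data frame with columns `time_s`, `to_channel`, `scheme`
#'   and `solute` (solution label), one row per switch, time-ordered; the
#'   `perfusions` table of an executed record (see
#'   [record_switches()]) has this shape.
#' @param dt time step, s.
#' @param t_end end of the simulated window, s.
#' @param initial_solute solute filling the line and chamber at t = 0
#'   (defaults to the first switch's solute, fresh).
#' @return data frame: `time_s`, `inflow_<solute>` fractions,
#'   `inflow_stale`, `chamber_<solute>` concentrations (fractions of chamber
#'   volume) and `chamber_stale`.
#' @export
advance_transport <- function(model, switches, dt = 0.5, t_end = NULL,
                              initial_solute = NULL) {
  stopifnot(inherits(model, "transport_model"), dt > 0)
  if (nrow(switches) == 0L) stop("no switches to simulate", call. = FALSE)
  switches <- switches[order(switches$time_s), , drop = FALSE]
  if (is.null(t_end)) t_end <- max(switches$time_s) + 60
  if (is.null(initial_solute)) initial_solute <- switches$solute[1L]

  q_mls <- model$flow_rate_ml_min / 60
  solutes <- unique(c(initial_solute, switches$solute))
  times <- seq(0, t_end, by = dt)

  # FIFO of plugs flowing toward the chamber; head enters the chamber first.
  plugs <- data.frame(volume = model$v_manifold_chamber,
                      solute = initial_solute, stale = 0,
                      stringsAsFactors = FALSE)
  source_solute <- initial_solute
  next_switch <- 1L

  inflow <- matrix(0, length(times), length(solutes),
                   dimnames = list(NULL, solutes))
  inflow_stale <- numeric(length(times))
  chamber <- matrix(0, length(times), length(solutes),
                    dimnames = list(NULL, solutes))
  chamber_stale <- numeric(length(times))
  conc <- stats::setNames(numeric(length(solutes)), solutes)
  conc[initial_solute] <- 1
  stale_conc <- 0

  for (k in seq_along(times)) {
    t0 <- times[k]
    # apply switches due by the start of this step
    while (next_switch <= nrow(switches) &&
           switches$time_s[next_switch] <= t0 + 1e-12) {
      sw <- switches[next_switch, ]
      vs <- stale_bolus_volume(model, sw$scheme)
      if (vs > 0)
        plugs <- rbind(plugs, data.frame(volume = vs, solute = sw$solute,
                                         stale = 1, stringsAsFactors = FALSE))
      source_solute <- sw$solute
      next_switch <- next_switch + 1L
    }
    # draw q*dt from the plug queue (head first), topping up from the source
    need <- q_mls * dt
    got <- stats::setNames(numeric(length(solutes)), solutes)
    got_stale <- 0
    while (need > 1e-15 && nrow(plugs) > 0L) {
      take <- min(need, plugs$volume[1L])
      got[plugs$solute[1L]] <- got[plugs$solute[1L]] + take
      got_stale <- got_stale + take * plugs$stale[1L]
      plugs$volume[1L] <- plugs$volume[1L] - take
      need <- need - take
      if (plugs$volume[1L] <= 1e-15) plugs <- plugs[-1L, , drop = FALSE]
    }
    if (need > 1e-15) {
      got[source_solute] <- got[source_solute] + need
      need <- 0
    }
    tot <- q_mls * dt
    x <- got / tot
    x_stale <- got_stale / tot
    inflow[k, ] <- x
    inflow_stale[k] <- x_stale
    # well-mixed chamber update (exact exponential over the step)
    f <- 1 - exp(-tot / model$chamber_volume_ml)
    conc <- conc + (x - conc) * f
    stale_conc <- stale_conc + (x_stale - stale_conc) * f
    chamber[k, ] <- conc
    chamber_stale[k] <- stale_conc
  }

  out <- data.frame(time_s = times, check.names = FALSE)
  for (s in solutes) out[[paste0("inflow_", s)]] <- inflow[, s]
  out$inflow_stale <- inflow_stale
  for (s in solutes) out[[paste0("chamber_", s)]] <- chamber[, s]
  out$chamber_stale <- chamber_stale
  out
}

# ---- trace synthesis --------------------------------------------------------

# Compactly supported fEPSP template per stimulus pulse: a small positive
# fiber volley (sin^2 bump, zero outside [volley_on, volley_off]) followed by
# a negative difference-of-exponentials synaptic deflection. The synaptic
# component is scaled so that the OLS slope over slope_window_ms (relative to
# the pulse) equals the requested slope exactly in the noiseless case.
fepsp_template <- function(t_rel_ms, slope, slope_window_ms,
                           tau_rise = 1.5, tau_decay = 8,
                           volley_on = 0.2, volley_off = 0.9,
                           volley_amp_per_slope = 0.2) {
  g <- ifelse(t_rel_ms > 0,
              exp(-t_rel_ms / tau_decay) - exp(-t_rel_ms / tau_rise), 0)
  in_win <- t_rel_ms >= slope_window_ms[1] & t_rel_ms <= slope_window_ms[2]
  if (sum(in_win) < 3L)
    stop("slope window contains fewer than 3 samples", call. = FALSE)
  s_g <- stats::cov(t_rel_ms[in_win], -g[in_win]) /
    stats::var(t_rel_ms[in_win])
  syn <- (slope / s_g) * (-g)
  vol <- numeric(length(t_rel_ms))
  iv <- t_rel_ms > volley_on & t_rel_ms < volley_off
  vol[iv] <- abs(slope) * volley_amp_per_slope *
    sin(pi * (t_rel_ms[iv] - volley_on) / (volley_off - volley_on))^2
  syn + vol
}

#' Synthesize a field-potential (AD0) sweep trace
#'
#' Each S0 stimulus pulse evokes a stereotyped fEPSP: a brief positive fiber
#' volley followed by a negative-going synaptic deflection whose initial
#' slope over the model's slope window equals `slope` exactly when
#' `noise_sd` is zero. Responses to train pulses superpose linearly.
#'
#' @param slice a [slice_model()].
#' @param sweep a [sweep_def()] (must contain at least one S0 pulse) or an
#'   already rendered `sweep_waveforms`.
#' @param slope current pathway slope, mV/ms (defaults to the model's
#'   baseline).
#' @param seed noise seed (defaults to the model's `rng_seed`).
#' @return a [trace()] in mV.
#' @export
synth_field_sweep <- function(slice, sweep, slope = slice$baseline_slope,
                              seed = slice$rng_seed) {
  w <- if (inherits(sweep, "sweep_waveforms")) sweep else render_sweep(sweep)
  if (length(w$s0_edges_ms) < 1L)
    stop("sweep has no S0 stimulus pulse", call. = FALSE)
  dt_ms <- 1000 / w$sample_rate_hz
  y <- numeric(length(w$t_ms))
  for (e in w$s0_edges_ms)
    y <- y + fepsp_template(w$t_ms - e, slope, slice$slope_window_ms)
  if (slice$noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(length(y), 0, slice$noise_sd))
  trace(y, dt_ms = dt_ms, units = "mV")
}

#' Synthesize an agonist-response (AD0 current) sweep trace
#'
#' The steady-state response to agonist concentration `c` in the presence of
#' competitive antagonist concentration `B` follows a Hill curve with a
#' Schild-shifted EC50: `Emax c^h / (c^h + (EC50 (1 + B/Ki))^h)`. The
#' current relaxes toward that target with first-order kinetics (`tau_on`
#' when activating, `tau_off` when deactivating), plus seeded Gaussian
#' noise.
#'
#' @param patch a [patch_model()].
#' @param agonist_conc,antagonist_conc concentration series (same units as
#'   `EC50` / `Ki`), one value per sample; `antagonist_conc` may be a scalar.
#' @param dt_ms sample interval of the series.
#' @param seed noise seed (defaults to the model's `rng_seed`).
#' @return a [trace()] in pA.
#' @export
synth_patch_sweep <- function(patch, agonist_conc, antagonist_conc = 0,
                              dt_ms = 0.1, seed = patch$rng_seed) {
  n <- length(agonist_conc)
  if (length(antagonist_conc) == 1L) antagonist_conc <- rep(antagonist_conc, n)
  stopifnot(length(antagonist_conc) == n, all(agonist_conc >= 0),
            all(antagonist_conc >= 0))
  ec50_app <- patch$EC50 * (1 + antagonist_conc / patch$Ki)
  ch <- agonist_conc^patch$hill_h
  target <- patch$Emax * ch / (ch + ec50_app^patch$hill_h)
  target[agonist_conc == 0] <- 0
  y <- numeric(n)
  cur <- 0
  for (k in seq_len(n)) {
    tau <- if (target[k] > cur) patch$tau_on_ms else patch$tau_off_ms
    cur <- cur + (target[k] - cur) * (1 - exp(-dt_ms / tau))
    y[k] <- cur
  }
  if (patch$noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(n, 0, patch$noise_sd))
  trace(y, dt_ms = dt_ms, units = "pA")
}

#' Synthesize a seal-test current transient
#'
#' The current response to a voltage step of `step_mV` across a series
#' resistance Rs into a membrane (Rin, Cm): an instantaneous peak
#' `step/Rs` decaying with time constant `tau = Rs Cm` toward the steady
#' state `step/(Rs + Rin)`. An optional slower second exponential component
#' (fraction `rs_second$frac` of the transient amplitude, time constant
#' `rs_second$tau_ms`) emulates imperfect capacitance compensation.
#'
#' @param patch a [patch_model()] (`Rs_MOhm` must be > 0).
#' @param step_mV voltage-step amplitude.
#' @param duration_ms trace duration.
#' @param sample_rate_hz sampling rate (default 50 kHz: the transient is
#'   fast, tau = Rs Cm is a fraction of a millisecond).
#' @param seed noise seed (defaults to the model's `rng_seed`).
#' @return a [trace()] in pA.
#' @export
synth_seal_test <- function(patch, step_mV, duration_ms = 5,
                            sample_rate_hz = 50000, seed = patch$rng_seed) {
  stopifnot(step_mV > 0, duration_ms > 0)
  if (patch$Rs_MOhm <= 0)
    stop("Rs must be > 0: the peak current step/Rs is unbounded otherwise",
         call. = FALSE)
  dt_ms <- 1000 / sample_rate_hz
  t_ms <- seq(0, duration_ms - dt_ms / 2, by = dt_ms)
  i_peak <- 1000 * step_mV / patch$Rs_MOhm                    # pA
  i_ss <- 1000 * step_mV / (patch$Rs_MOhm + patch$Rin_MOhm)   # pA
  tau_ms <- patch$Rs_MOhm * patch$Cm_pF / 1000
  a_tot <- i_peak - i_ss
  if (is.null(patch$rs_second)) {
    y <- i_ss + a_tot * exp(-t_ms / tau_ms)
  } else {
    f2 <- patch$rs_second$frac
    y <- i_ss + a_tot * ((1 - f2) * exp(-t_ms / tau_ms) +
                           f2 * exp(-t_ms / patch$rs_second$tau_ms))
  }
  if (patch$noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(length(y), 0, patch$noise_sd))
  trace(y, dt_ms = dt_ms, units = "pA")
}
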