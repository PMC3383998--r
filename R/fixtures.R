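# Worked-example rigs and protocol scripts. The protocol files ship under
# inst/extdata/protocols/ in the package's text dialect; the rigs are built
# here in code.

#' Worked-example rig configurations
#'
#' \describe{
#'   \item{slice}{one slow line (Slow0, 8-channel valvebits controller on
#'     Port1, standard switching, pinch valves), single-pulse `P0sweep` and
#'     100-pulse `T0sweep` at 10 ms intervals, 30 s sweep pacing, bubbled
#'     slice plumbing (reservoir 40 cm above a 9 cm junction-to-manifold
#'     run, 0.8 mm ID, 2 ml/min into a 1 ml chamber) and a [slice_model()]
#'     whose channel-2 solution blocks induction.}
#'   \item{slice_preflush}{as `slice` but a 4-channel pre-flush controller
#'     (2 valves/channel, chamber valves bits 0-3, flush valves bits 4-7).}
#'   \item{patch8}{single-line fast perfusion: Fast0 8-channel analog
#'     controller (1 V/channel) on AnalogOut1, fast valves, four sweeps with
#'     three IC1 epochs (0.5 s hold, 1 s application, 0.5 s hold), 5 s
#'     pacing, and a [patch_model()].}
#'   \item{patch16}{as `patch8` but a 16-channel controller at
#'     0.5 V/channel, for linked-protocol designs needing 15 solutions.}
#'   \item{stepper}{triple-line stepper rig: Slow0 and Slow1 valvebits
#'     controllers on Ports 1 and 2, Fast1 4-bit binary on Port0, and Fast0
#'     driving the stepper (analog, 1 V/tube; channels 0-2 are tubes 0-2);
#'     `P0sweep` steps to Tube0 during its middle epoch, `P1sweep` to
#'     Tube2.}
#' }
#'
#' @param name rig name (see above).
#' @return a [rig_config()].
#' @export
fixture_rig <- function(name = c("slice", "slice_preflush", "patch8",
                                 "patch16", "stepper")) {
  name <- match.arg(name)
  slice_tubing <- list(
    tubing_segment(40, 0.8, "reservoir_to_junction"),
    tubing_segment(9, 0.8, "junction_to_manifold"),
    tubing_segment(5, 0.8, "manifold_to_chamber"))
  slice_sweeps <- list(
    P0sweep = sweep_def("P0sweep", duration_ms = 200,
                        s0_train = pulse_train(10, 1)),
    T0sweep = sweep_def("T0sweep", duration_ms = 1100,
                        s0_train = pulse_train(10, 100, interval_ms = 10)))
  patch_epochs <- data.frame(duration_ms = c(500, 1000, 500),
                             amplitude = c(-1, -1, -1))
  patch_sweeps <- function() {
    out <- lapply(SWEEP_NAMES, function(nm)
      sweep_def(nm, duration_ms = 3000, sample_rate_hz = 1000,
                ic1_epochs = patch_epochs))
    stats::setNames(out, SWEEP_NAMES)
  }
  switch(name,
    slice = rig_config(
      controllers = list(Slow0 = controller_config(
        "Slow0", mode = "valvebits", n_channels = 8, port = "Port1")),
      sweep_defs = slice_sweeps,
      tubing = list(Slow0 = slice_tubing),
      slice = slice_model()),
    slice_preflush = rig_config(
      controllers = list(Slow0 = controller_config(
        "Slow0", mode = "valvebits", n_channels = 4, valves_per_channel = 2,
        port = "Port1")),
      sweep_defs = slice_sweeps,
      tubing = list(Slow0 = slice_tubing),
      slice = slice_model()),
    patch8 = rig_config(
      controllers = list(Fast0 = controller_config(
        "Fast0", mode = "analog", n_channels = 8, volts_per_channel = 1,
        port = "AnalogOut1", valve_switch_time_ms = 4)),
      sweep_defs = patch_sweeps(),
      inter_sweep_interval_s = 5,
      patch = patch_model()),
    patch16 = rig_config(
      controllers = list(Fast0 = controller_config(
        "Fast0", mode = "analog", n_channels = 16, volts_per_channel = 0.5,
        port = "AnalogOut1", valve_switch_time_ms = 4)),
      sweep_defs = patch_sweeps(),
      inter_sweep_interval_s = 5,
      patch = patch_model()),
    stepper = {
      p_sweeps <- patch_sweeps()[c("P0sweep", "P1sweep")]
      rig_config(
        controllers = list(
          Slow0 = controller_config("Slow0", mode = "valvebits",
                                    n_channels = 8, port = "Port1"),
          Slow1 = controller_config("Slow1", mode = "valvebits",
                                    n_channels = 8, port = "Port2"),
          Fast1 = controller_config("Fast1", mode = "binary4",
                                    n_channels = 8, port = "Port0",
                                    binary_convention = "8ch"),
          Fast0 = controller_config("Fast0", mode = "analog", n_channels = 2,
                                    volts_per_channel = 1,
                                    port = "AnalogOut1")),
        sweep_defs = p_sweeps,
        inter_sweep_interval_s = 5,
        patch = patch_model(),
        stepper = stepper_config())
    })
}

#' Worked-example protocol scripts shipped with the package
#'
#' \describe{
#'   \item{ltp_circular}{a continuous baseline loop; the operator evokes
#'     train sweeps manually (`single_sweep` controls).}
#'   \item{ltp_runonce}{the baseline loop contains a RunOnce block with one
#'     train sweep, run once per `check_runonce` control.}
#'   \item{ltp_sequential}{sequential script: baseline loop exited by an
#'     uncheck, a train, 11 single-pulse loops, a second train, 8 more.}
#'   \item{ltp_perfusion}{the sequential LTP experiment with automated
#'     perfusion: ACSF baseline, switch to a CaMKII-inhibitor solution, a
#'     train in inhibitor, washout, a second train in ACSF.}
#'   \item{single_line_fast}{single-line patch protocol: four ongoing
#'     antagonist channels, each with four agonist applications delivered by
#'     within-sweep epochs on channels 5-8.}
#'   \item{linked_antag1/2/3}{three linked protocols covering 3 antagonist
#'     channels and 12 agonist+antagonist channels (15 solutions).}
#'   \item{stepper_triple}{triple-line stepper protocol: antagonist on
#'     Tube1, agonists on Tube0/Tube2, momentary stepper moves during
#'     sweeps.}
#' }
#'
#' @param name fixture name (file stem).
#' @return a [protocol_script()] (for `linked_antag1` follow the chain with
#'   [load_protocol_chain()] on [fixture_protocol_path()]).
#' @export
fixture_protocol <- function(name = c("ltp_circular", "ltp_runonce",
                                      "ltp_sequential", "ltp_perfusion",
                                      "single_line_fast", "linked_antag1",
                                      "linked_antag2", "linked_antag3",
                                      "stepper_triple")) {
  read_protocol(fixture_protocol_path(match.arg(name)))
}

#' Path of a shipped protocol fixture file
#' @param name fixture name (see [fixture_protocol()]).
#' @return file path in the installed package.
#' @export
fixture_protocol_path <- function(name) {
  p <- system.file("extdata", "protocols", paste0(name, ".proto"),
                   package = "perfusim", mustWork = TRUE)
  p
}
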