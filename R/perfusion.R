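# Perfusion-controller configuration, channel -> output encodings, and
# valve-action planning for the supported switching schemes.

#' Perfusion line identifiers
#'
#' The rig exposes exactly four logical perfusion lines. `Slow0` and `Slow1`
#' drive static digital ports and can change solution only between sweeps;
#' `Fast0` and `Fast1` drive the high-speed port (or an analog output) and can
#' also change solution during a sweep.
#'
#' @format Character vector of the four line ids.
#' @export
PERFUSION_LINES <- c("Slow0", "Slow1", "Fast0", "Fast1")

#' Is a line a fast (within-sweep capable) line?
#' @param line a perfusion line id.
#' @return logical.
#' @export
is_fast_line <- function(line) {
  line <- match.arg(line, PERFUSION_LINES)
  line %in% c("Fast0", "Fast1")
}

#' Describe a perfusion valve controller
#'
#' A controller converts a perfusion *channel number* into physical output:
#' an analog voltage (`analog` mode, one valve open at a time), a 4-bit
#' binary code (`binary4`, one valve open at a time), or one bit per valve
#' (`valvebits`, several valves may be open at once, which pre-flush
#' switching requires).
#'
#' @param line perfusion line id (`"Slow0"`, `"Slow1"`, `"Fast0"`, `"Fast1"`).
#' @param mode `"analog"`, `"binary4"` or `"valvebits"`.
#' @param n_channels number of channels (typically 4, 8, 15 or 16).
#' @param volts_per_channel analog spacing; by convention 1 V/channel for
#'   8-channel controllers and 0.5 V/channel for 16-channel controllers.
#' @param valves_per_channel 1 for standard or continuous-flow-to-waste
#'   plumbing, 2 for pre-flush (a chamber valve plus a flush valve).
#' @param port output port: `"Port0"` (high-speed), `"Port1"`, `"Port2"`,
#'   `"Port1+2"` (16-bit), or `"AnalogOut1"`/`"AnalogOut2"`.
#' @param bit_base first bit index used on the port.
#' @param valve_switch_time_ms mechanical switching latency; around 100 ms
#'   for pinch valves, around 4 ms for Lee-style fast valves.
#' @param binary_convention for `binary4` mode: `"8ch"` (codes 0-8, 0 = off),
#'   `"off_code_zero_15ch"` (codes 0-15, 0 reserved for all-off) or
#'   `"full_16ch"` (codes 0-15 are channels 1-16, no off code).
#' @param amplitude_units how sweep-epoch amplitudes are interpreted for this
#'   controller: `"channel"` (one unit selects one channel, converted by
#'   `volts_per_channel` at the output) or `"volts"` (literal volts).
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(line = "Slow0",
                              mode = c("valvebits", "analog", "binary4"),
                              n_channels = 8,
                              volts_per_channel = if (n_channels > 8) 0.5 else 1.0,
                              valves_per_channel = 1,
                              port = "Port1",
                              bit_base = 0L,
                              valve_switch_time_ms = 100,
                              binary_convention = c("8ch", "off_code_zero_15ch", "full_16ch"),
                              amplitude_units = c("channel", "volts")) {
  line <- match.arg(line, PERFUSION_LINES)
  mode <- match.arg(mode)
  binary_convention <- match.arg(binary_convention)
  amplitude_units <- match.arg(amplitude_units)
  stopifnot(n_channels >= 1, volts_per_channel > 0,
            valves_per_channel %in% c(1L, 2L), valve_switch_time_ms >= 0)
  port_bits <- if (identical(port, "Port1+2")) 16L else 8L
  if (mode == "valvebits" && valves_per_channel == 2L &&
      n_channels > port_bits / 2L) {
    stop("pre-flush (2 valves/channel) on ", port, " supports at most ",
         port_bits / 2L, " channels", call. = FALSE)
  }
  structure(
    list(line = line, mode = mode, n_channels = as.integer(n_channels),
         volts_per_channel = volts_per_channel,
         valves_per_channel = as.integer(valves_per_channel),
         port = port, bit_base = as.integer(bit_base),
         valve_switch_time_ms = valve_switch_time_ms,
         binary_convention = binary_convention,
         amplitude_units = amplitude_units),
    class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("<controller_config> %s: %d-channel %s on %s", x$line,
              x$n_channels, x$mode, x$port))
  if (x$mode == "analog") cat(sprintf(" (%g V/channel)", x$volts_per_channel))
  if (x$valves_per_channel == 2L) cat(" [pre-flush, 2 valves/channel]")
  cat("\n")
  invisible(x)
}

check_channel <- function(channel, n_channels, allow_zero = TRUE) {
  if (length(channel) != 1L || is.na(channel) || channel != as.integer(channel))
    stop("channel must be a single integer", call. = FALSE)
  lo <- if (allow_zero) 0L else 1L
  if (channel < lo || channel > n_channels)
    stop("channel ", channel, " out of range [", lo, ", ", n_channels, "]",
         call. = FALSE)
  as.integer(channel)
}

#' Encode a channel number as an analog controller voltage
#'
#' Analog-input controllers open the valve whose index matches the command
#' voltage divided by the per-channel spacing; channel 0 (0 V) is all-off.
#'
#' @param channel integer channel, 0 (all off) to `cfg$n_channels`.
#' @param cfg a [controller_config()].
#' @return voltage (numeric scalar).
#' @examples
#' encode_analog(8, controller_config(mode = "analog", n_channels = 8))  # 8 V
#' @export
encode_analog <- function(channel, cfg) {
  channel <- check_channel(channel, cfg$n_channels)
  channel * cfg$volts_per_channel
}

#' Encode a channel number as a 4-bit binary code
#'
#' Four sync bits on the high-speed port can address 8, 15 or 16 channels
#' with one valve open at a time; the conventions differ in whether code
#' 0000 is reserved for all-off.
#'
#' @param channel integer channel number.
#' @param convention `"8ch"` (0-8, code = channel), `"off_code_zero_15ch"`
#'   (0-15, code = channel, 0 = off), or `"full_16ch"` (1-16, code =
#'   channel - 1; no off code).
#' @return integer vector of 4 bits, most significant first.
#' @export
encode_binary4 <- function(channel,
                           convention = c("8ch", "off_code_zero_15ch", "full_16ch")) {
  convention <- match.arg(convention)
  code <- switch(convention,
    "8ch" = check_channel(channel, 8L),
    "off_code_zero_15ch" = check_channel(channel, 15L),
    "full_16ch" = check_channel(channel, 16L, allow_zero = FALSE) - 1L)
  as.integer(intToBits(code))[4:1]
}

#' Format a 4-bit code as a string such as "0101"
#' @param bits integer vector as returned by [encode_binary4()].
#' @return character scalar.
#' @export
format_bits <- function(bits) paste(bits, collapse = "")

#' Encode a channel as a one-valve-per-bit byte
#'
#' In `valvebits` mode channel n maps to bit n-1 of the port (channel 1 is
#' bit 0, channel 2 is bit 1, ...); channel 0 clears all bits.
#'
#' @param channel integer channel, 0 to `cfg$n_channels`.
#' @param cfg a [controller_config()] in valvebits mode.
#' @return integer byte value (0-255 on an 8-bit port).
#' @export
encode_valvebits <- function(channel, cfg) {
  channel <- check_channel(channel, cfg$n_channels)
  if (channel == 0L) 0L else bitwShiftL(1L, cfg$bit_base + channel - 1L)
}

new_switch_plan <- function(actions, from_channel, to_channel, mode) {
  if (is.null(actions) || nrow(actions) == 0L) {
    actions <- data.frame(time_s = numeric(), port = character(),
                          kind = character(), bit = integer(),
                          value = numeric(), stringsAsFactors = FALSE)
  }
  actions <- actions[order(actions$time_s), , drop = FALSE]
  rownames(actions) <- NULL
  structure(actions, class = c("switch_plan", "data.frame"),
            from_channel = from_channel, to_channel = to_channel, mode = mode)
}

#' @export
print.switch_plan <- function(x, ...) {
  cat(sprintf("<switch_plan> Ch%d -> Ch%d (%s), %d action(s)\n",
              attr(x, "from_channel"), attr(x, "to_channel"),
              attr(x, "mode"), nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

bit_action <- function(time_s, port, bit, on) {
  data.frame(time_s = time_s, port = port, kind = "bit", bit = as.integer(bit),
             value = as.numeric(on), stringsAsFactors = FALSE)
}

analog_action <- function(time_s, port, volts) {
  data.frame(time_s = time_s, port = port, kind = "analog", bit = NA_integer_,
             value = volts, stringsAsFactors = FALSE)
}

#' Plan a standard (one valve per line) perfusion switch
#'
#' In the standard scheme the outgoing channel's valve closes and the target
#' channel's valve opens simultaneously, so the whole reservoir-to-manifold
#' dead volume of the incoming line is delivered as a stale bolus.
#'
#' @param from_ch,to_ch channel numbers (0 = all off).
#' @param cfg a [controller_config()].
#' @return a `switch_plan`: ordered valve/voltage actions.
#' @examples
#' cfg <- controller_config(mode = "valvebits", n_channels = 8)
#' plan_standard_switch(1, 2, cfg)  # bit0 off and bit1 on at t = 0
#' @export
plan_standard_switch <- function(from_ch, to_ch, cfg) {
  from_ch <- check_channel(from_ch, cfg$n_channels)
  to_ch <- check_channel(to_ch, cfg$n_channels)
  if (from_ch == to_ch)
    return(new_switch_plan(NULL, from_ch, to_ch, "standard"))
  acts <- switch(cfg$mode,
    valvebits = {
      a <- NULL
      if (from_ch > 0L)
        a <- rbind(a, bit_action(0, cfg$port, cfg$bit_base + from_ch - 1L, FALSE))
      if (to_ch > 0L)
        a <- rbind(a, bit_action(0, cfg$port, cfg$bit_base + to_ch - 1L, TRUE))
      a
    },
    analog = analog_action(0, cfg$port, encode_analog(to_ch, cfg)),
    binary4 = {
      bits <- encode_binary4(to_ch, cfg$binary_convention)
      do.call(rbind, lapply(0:3, function(i)
        bit_action(0, cfg$port, cfg$bit_base + i, bits[4L - i])))
    })
  new_switch_plan(acts, from_ch, to_ch, "standard")
}

#' Plan a pre-flush perfusion switch
#'
#' Pre-flush plumbing uses two valves per line: a chamber valve (bits
#' `bit_base` ... `bit_base + n - 1` for channels 1..n) and a flush-to-waste
#' valve (bits `bit_base + n` ...). The incoming line is first flushed to
#' waste to clear stale solution between the reservoir and the T-junction;
#' at switch-over the flush valve closes, the incoming chamber valve opens
#' and the outgoing chamber valve closes, all simultaneously. Only the
#' T-junction-to-manifold volume then reaches the chamber stale.
#'
#' @param from_ch,to_ch channel numbers (1-based; `to_ch` must be a real
#'   channel).
#' @param flush_duration_s how long the flush valve stays open (must be > 0).
#' @param cfg a [controller_config()] with `valves_per_channel = 2`.
#' @return a `switch_plan`.
#' @export
plan_preflush_switch <- function(from_ch, to_ch, flush_duration_s, cfg) {
  if (cfg$valves_per_channel != 2L)
    stop("pre-flush switching requires a 2-valves-per-channel controller",
         call. = FALSE)
  if (flush_duration_s <= 0) stop("flush_duration_s must be > 0", call. = FALSE)
  from_ch <- check_channel(from_ch, cfg$n_channels)
  to_ch <- check_channel(to_ch, cfg$n_channels, allow_zero = FALSE)
  if (from_ch == to_ch)
    return(new_switch_plan(NULL, from_ch, to_ch, "preflush"))
  chamber_bit <- function(ch) cfg$bit_base + ch - 1L
  flush_bit <- function(ch) cfg$bit_base + cfg$n_channels + ch - 1L
  acts <- rbind(
    bit_action(0, cfg$port, flush_bit(to_ch), TRUE),
    bit_action(flush_duration_s, cfg$port, flush_bit(to_ch), FALSE),
    bit_action(flush_duration_s, cfg$port, chamber_bit(to_ch), TRUE),
    if (from_ch > 0L)
      bit_action(flush_duration_s, cfg$port, chamber_bit(from_ch), FALSE))
  new_switch_plan(acts, from_ch, to_ch, "preflush")
}

#' Plan a continuous-flow-to-waste perfusion switch
#'
#' Each line runs through a three-way normally-open/normally-closed valve:
#' deactivated, the line flows continuously to waste (so it never goes
#' stale upstream of the Y-junction); activated, flow is diverted from the
#' Y-junction to the manifold. A switch is a single simultaneous toggle.
#'
#' @param from_ch,to_ch channel numbers (0 = all off / all to waste).
#' @param cfg a [controller_config()] (one valve per channel).
#' @return a `switch_plan`.
#' @export
plan_flow_to_waste_switch <- function(from_ch, to_ch, cfg) {
  from_ch <- check_channel(from_ch, cfg$n_channels)
  to_ch <- check_channel(to_ch, cfg$n_channels)
  if (from_ch == to_ch)
    return(new_switch_plan(NULL, from_ch, to_ch, "flow_to_waste"))
  a <- NULL
  if (from_ch > 0L)
    a <- rbind(a, bit_action(0, cfg$port, cfg$bit_base + from_ch - 1L, FALSE))
  if (to_ch > 0L)
    a <- rbind(a, bit_action(0, cfg$port, cfg$bit_base + to_ch - 1L, TRUE))
  new_switch_plan(a, from_ch, to_ch, "flow_to_waste")
}

#' Final chamber-valve state after a switch plan
#'
#' Applies a plan's bit actions to an initial open-valve set and returns the
#' channels whose chamber valve is open afterwards (for analog plans, the
#' channel selected by the final voltage). Used to check the one-open-valve
#' invariant.
#'
#' @param plan a `switch_plan`.
#' @param cfg the [controller_config()] the plan was made for.
#' @param initial_open integer vector of initially open chamber channels
#'   (defaults to the plan's `from_channel` if nonzero).
#' @return integer vector of open chamber channels (length 0 or 1 after any
#'   valid plan).
#' @export
open_chamber_channels <- function(plan, cfg, initial_open = NULL) {
  from <- attr(plan, "from_channel")
  if (is.null(initial_open)) initial_open <- if (from > 0L) from else integer()
  if (cfg$mode == "analog") {
    av <- plan[plan$kind == "analog", , drop = FALSE]
    if (nrow(av) == 0L) return(initial_open)
    ch <- as.integer(round(av$value[nrow(av)] / cfg$volts_per_channel))
    return(if (ch > 0L) ch else integer())
  }
  open <- rep(FALSE, cfg$n_channels)
  open[initial_open] <- TRUE
  ba <- plan[plan$kind == "bit", , drop = FALSE]
  chamber_bits <- cfg$bit_base + seq_len(cfg$n_channels) - 1L
  for (i in seq_len(nrow(ba))) {
    idx <- match(ba$bit[i], chamber_bits)
    if (!is.na(idx)) open[idx] <- ba$value[i] > 0
  }
  which(open)
}

#' Stepper tube selection as a Fast0 analog action
#'
#' Dual- and triple-line patch-clamp rigs mount two or three outflow tubes
#' side by side on a stepper; the `Fast0` analog output positions the
#' stepper so a given tube's stream bathes the cell (1 V per tube index).
#'
#' @param tube tube index 0, 1 or 2.
#' @param cfg a [stepper_config()].
#' @return one-row action data frame (time 0, analog value in volts).
#' @export
stepper_move <- function(tube, cfg) {
  if (!(tube %in% cfg$tubes))
    stop("tube ", tube, " is not configured on this stepper", call. = FALSE)
  analog_action(0, "Fast0", tube * cfg$fast0_volts_per_tube)
}

#' Describe a stepper for dual- or triple-line fast perfusion
#'
#' @param tubes tube indices present (dual-line rigs omit tube 2). Feeding
#'   lines by convention: Tube0 from Slow0, Tube1 from Slow1, Tube2 from
#'   Fast1.
#' @param fast0_volts_per_tube analog volts per tube position (1 V).
#' @param move_time_ms time to step between adjacent tubes (about 1 ms for
#'   a piezo stepper).
#' @return an object of class `stepper_config`.
#' @export
stepper_config <- function(tubes = 0:2, fast0_volts_per_tube = 1,
                           move_time_ms = 1) {
  stopifnot(all(tubes %in% 0:2), fast0_volts_per_tube > 0, move_time_ms >= 0)
  structure(list(tubes = as.integer(tubes),
                 fast0_volts_per_tube = fast0_volts_per_tube,
                 move_time_ms = move_time_ms),
            class = "stepper_config")
}

#' Describe a tubing segment
#'
#' @param length_cm segment length in cm.
#' @param inner_diameter_mm inner diameter in mm (1/32 inch is about 0.8 mm).
#' @param role one of `"reservoir_to_junction"`, `"junction_to_manifold"`,
#'   `"manifold_to_chamber"`.
#' @return an object of class `tubing_segment`.
#' @export
tubing_segment <- function(length_cm, inner_diameter_mm,
                           role = c("junction_to_manifold",
                                    "reservoir_to_junction",
                                    "manifold_to_chamber")) {
  role <- match.arg(role)
  stopifnot(length_cm >= 0, inner_diameter_mm > 0)
  structure(list(length_cm = length_cm,
                 inner_diameter_mm = inner_diameter_mm, role = role),
            class = "tubing_segment")
}

#' Dead volume of a tubing segment
#'
#' The cylinder volume pi (d/2)^2 L, reported in ml. For 0.8 mm ID tubing
#' this gives about 0.05 ml per 9 cm and 0.08 ml per 16 cm -- the stale
#' volume between the T/Y junction and the manifold in 4- and 8-channel
#' systems respectively.
#'
#' @param seg a [tubing_segment()].
#' @return volume in ml.
#' @export
dead_volume <- function(seg) {
  r_cm <- seg$inner_diameter_mm / 20   # mm diameter -> cm radius
  pi * r_cm^2 * seg$length_cm          # cm^3 == ml
}

#' Solutions needed for an agonist/antagonist concentration-response design
#'
#' If the antagonist stays bound during agonist application, agonist and
#' antagonist solutions are independent and the design needs
#' `n_agonists + n_antagonists` solutions. If the antagonist is displaced,
#' every agonist solution must also contain the antagonist, so each
#' (agonist, antagonist) pair needs its own solution:
#' `n_antagonists + n_agonists * n_antagonists`.
#'
#' @param n_agonists,n_antagonists numbers of concentrations tested.
#' @param antagonist_stays_bound logical.
#' @return integer solution (and valve) count.
#' @examples
#' solutions_required(4, 4, TRUE)    # 8: one 8-valve controller suffices
#' solutions_required(4, 3, FALSE)   # 15: needs a 16-channel controller
#' @export
solutions_required <- function(n_agonists, n_antagonists,
                               antagonist_stays_bound) {
  stopifnot(n_agonists >= 0, n_antagonists >= 0,
            is.logical(antagonist_stays_bound))
  if (antagonist_stays_bound) as.integer(n_agonists + n_antagonists)
  else as.integer(n_antagonists + n_agonists * n_antagonists)
}

#' Maximum solutions addressable by a multi-line stepper rig
#'
#' @param lines number of perfusion lines feeding stepper tubes (1-3).
#' @param channels_per_line valve count per line's controller.
#' @return integer; e.g. 48 for a triple-line rig of 16-channel controllers.
#' @export
max_solutions <- function(lines, channels_per_line) {
  stopifnot(lines %in% 1:3, channels_per_line >= 1)
  as.integer(lines * channels_per_line)
}
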