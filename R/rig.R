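# Rig configuration: controllers per perfusion line, sweep definitions,
# plumbing (switching scheme, tubing, flow), timing defaults, and the
# virtual-biology models. Serializable to/from YAML.

#' Assemble a rig configuration
#'
#' @param controllers named list of [controller_config()]s, keyed by
#'   perfusion line id.
#' @param sweep_defs named list of [sweep_def()]s, keyed by sweep name.
#' @param scheme named character: switching scheme per line, each one of
#'   `"standard"`, `"preflush"`, `"flow_to_waste"`. Lines absent from the map
#'   default to `"standard"` (or `"preflush"` when the controller has two
#'   valves per channel).
#' @param tubing named list per line: list of [tubing_segment()]s.
#' @param flow_rate_ml_min perfusion flow rate.
#' @param chamber_volume_ml recording-chamber volume (well-mixed
#'   compartment).
#' @param inter_sweep_interval_s gap between consecutive sweeps (default 30 s
#'   baseline pacing).
#' @param flush_duration_s how long a pre-flush valve stays open before
#'   switch-over.
#' @param slow_port_jitter_ms latency-jitter bound for slow-port valve
#'   actions (static ports are accurate to milliseconds or tens of
#'   milliseconds; 0 disables jitter, capped at 50 ms). Fast-port actions
#'   are exact.
#' @param slice optional [slice_model()].
#' @param patch optional [patch_model()].
#' @param stepper optional [stepper_config()].
#' @return an object of class `rig_config`.
#' @export
rig_config <- function(controllers = list(), sweep_defs = list(),
                       scheme = character(), tubing = list(),
                       flow_rate_ml_min = 2, chamber_volume_ml = 1,
                       inter_sweep_interval_s = 30, flush_duration_s = 10,
                       slow_port_jitter_ms = 0,
                       slice = NULL, patch = NULL, stepper = NULL) {
  stopifnot(all(names(controllers) %in% PERFUSION_LINES),
            all(vapply(controllers, inherits, TRUE, "controller_config")),
            all(vapply(sweep_defs, inherits, TRUE, "sweep_def")),
            flow_rate_ml_min > 0, chamber_volume_ml > 0,
            inter_sweep_interval_s >= 0, flush_duration_s > 0,
            slow_port_jitter_ms >= 0, slow_port_jitter_ms <= 50)
  full_scheme <- vapply(names(controllers), function(ln) {
    if (ln %in% names(scheme)) {
      match.arg(scheme[[ln]], c("standard", "preflush", "flow_to_waste"))
    } else if (controllers[[ln]]$valves_per_channel == 2L) "preflush"
    else "standard"
  }, "")
  names(full_scheme) <- names(controllers)
  structure(list(controllers = controllers, sweep_defs = sweep_defs,
                 scheme = full_scheme, tubing = tubing,
                 flow_rate_ml_min = flow_rate_ml_min,
                 chamber_volume_ml = chamber_volume_ml,
                 inter_sweep_interval_s = inter_sweep_interval_s,
                 flush_duration_s = flush_duration_s,
                 slow_port_jitter_ms = slow_port_jitter_ms,
                 slice = slice, patch = patch, stepper = stepper),
            class = "rig_config")
}

#' @export
print.rig_config <- function(x, ...) {
  cat(sprintf("<rig_config> %d controller(s): %s; sweeps: %s\n",
              length(x$controllers),
              paste(names(x$controllers), collapse = ", "),
              paste(names(x$sweep_defs), collapse = ", ")))
  cat(sprintf("  flow %g ml/min, chamber %g ml, inter-sweep %g s\n",
              x$flow_rate_ml_min, x$chamber_volume_ml,
              x$inter_sweep_interval_s))
  invisible(x)
}

#' Plan the valve actions realizing a channel change on a rig line
#'
#' Dispatches to [plan_standard_switch()], [plan_preflush_switch()] or
#' [plan_flow_to_waste_switch()] according to the line's configured scheme.
#'
#' @param rig a [rig_config()].
#' @param line perfusion line id.
#' @param from_ch,to_ch channel numbers.
#' @return a `switch_plan`.
#' @export
plan_switch <- function(rig, line, from_ch, to_ch) {
  cfg <- rig$controllers[[line]]
  if (is.null(cfg)) stop("no controller configured for line ", line,
                         call. = FALSE)
  switch(rig$scheme[[line]],
    standard = plan_standard_switch(from_ch, to_ch, cfg),
    preflush = plan_preflush_switch(from_ch, to_ch, rig$flush_duration_s, cfg),
    flow_to_waste = plan_flow_to_waste_switch(from_ch, to_ch, cfg))
}

# ---- YAML serialization -----------------------------------------------------

seg_to_list <- function(s) unclass(s)

sweep_to_list <- function(s) {
  out <- unclass(s)
  for (f in c("s0_train", "s1_train"))
    if (!is.null(out[[f]])) out[[f]] <- unclass(out[[f]])
  if (!is.null(out$ic0_steps)) out$ic0_steps <- as.list(out$ic0_steps)
  if (!is.null(out$ic1_epochs)) out$ic1_epochs <- as.list(out$ic1_epochs)
  out
}

sweep_from_list <- function(l) {
  mk_train <- function(t) if (is.null(t)) NULL else do.call(pulse_train, t)
  sweep_def(name = l$name, duration_ms = l$duration_ms,
            sample_rate_hz = l$sample_rate_hz,
            s0_train = mk_train(l$s0_train), s1_train = mk_train(l$s1_train),
            ic0_steps = if (is.null(l$ic0_steps)) NULL
                        else as.data.frame(l$ic0_steps),
            ic1_epochs = if (is.null(l$ic1_epochs)) NULL
                         else as.data.frame(l$ic1_epochs))
}

#' Write a rig configuration to a YAML file
#' @param rig a [rig_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rig <- function(rig, path) {
  l <- list(
    controllers = lapply(rig$controllers, unclass),
    sweep_defs = lapply(rig$sweep_defs, sweep_to_list),
    scheme = as.list(rig$scheme),
    tubing = lapply(rig$tubing, function(segs) lapply(segs, seg_to_list)),
    flow_rate_ml_min = rig$flow_rate_ml_min,
    chamber_volume_ml = rig$chamber_volume_ml,
    inter_sweep_interval_s = rig$inter_sweep_interval_s,
    flush_duration_s = rig$flush_duration_s,
    slow_port_jitter_ms = rig$slow_port_jitter_ms,
    biology = list(
      slice = if (!is.null(rig$slice)) unclass(rig$slice),
      patch = if (!is.null(rig$patch)) unclass(rig$patch)),
    stepper = if (!is.null(rig$stepper)) unclass(rig$stepper))
  yaml::write_yaml(l, path)
  invisible(path)
}

#' Read a rig configuration from a YAML file
#' @param path file path.
#' @return a [rig_config()].
#' @export
read_rig <- function(path) {
  l <- yaml::read_yaml(path)
  controllers <- lapply(l$controllers, function(cc) do.call(controller_config, cc))
  sweep_defs <- lapply(l$sweep_defs, sweep_from_list)
  tubing <- lapply(l$tubing, function(segs)
    lapply(segs, function(s) do.call(tubing_segment, s)))
  rig_config(
    controllers = controllers, sweep_defs = sweep_defs,
    scheme = unlist(l$scheme %||% list()),
    tubing = tubing,
    flow_rate_ml_min = l$flow_rate_ml_min %||% 2,
    chamber_volume_ml = l$chamber_volume_ml %||% 1,
    inter_sweep_interval_s = l$inter_sweep_interval_s %||% 30,
    flush_duration_s = l$flush_duration_s %||% 10,
    slow_port_jitter_ms = l$slow_port_jitter_ms %||% 0,
    slice = if (!is.null(l$biology$slice))
      do.call(slice_model, l$biology$slice),
    patch = if (!is.null(l$biology$patch))
      do.call(patch_model, l$biology$patch),
    stepper = if (!is.null(l$stepper)) do.call(stepper_config, l$stepper))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
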