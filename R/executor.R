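# Discrete-event protocol interpreter: runs protocol scripts against a rig
# configuration, applying simulated operator actions (loop unchecks, RunOnce
# checks, manual/override perfusion), handling protocol linking, and
# emitting the experimental log. Simulated wall time is dimensionless
# seconds; nothing sleeps.

#' Simulated operator action
#'
#' Control events stand in for the operator's interactions with the running
#' program. Each has a trigger -- a wall-clock time (`at_time`, seconds) or
#' a completed-sweep count (`after_sweep`) -- and an action:
#' \describe{
#'   \item{uncheck_loop}{exit continuous loop number `loop_index` (loops are
#'     numbered in script order); the exit is taken at the end of the
#'     current iteration.}
#'   \item{check_runonce}{run the body of RunOnce block `runonce_index` once
#'     at its next encounter.}
#'   \item{single_sweep}{manually evoke one `sweep_name` sweep.}
#'   \item{set_override}{`channel` given: switch manual override on and
#'     apply that channel on `line`; `channel = NULL`: override off.
#'     While override is on, scripted Perfuse events are suppressed.}
#'   \item{manual_apply}{apply `channel` on `line`; rejected with a logged
#'     warning while a protocol is running without override.}
#'   \item{set_ch_to_last_perfuse}{`value = TRUE`: leave the last perfused
#'     channel on when the protocol finishes (instead of switching all
#'     lines off).}
#'   \item{start_protocol}{start linked protocol number `protocol` when its
#'     autostart flag is unset.}
#' }
#'
#' @param action action name (see above).
#' @param at_time wall-time trigger, seconds (NULL = no time trigger).
#' @param after_sweep trigger once this many sweeps have completed.
#' @param loop_index,runonce_index,sweep_name,line,channel,value,protocol
#'   action arguments.
#' @return an object of class `control_event`.
#' @export
control_event <- function(action = c("uncheck_loop", "check_runonce",
                                     "single_sweep", "set_override",
                                     "manual_apply", "set_ch_to_last_perfuse",
                                     "start_protocol"),
                          at_time = NULL, after_sweep = NULL,
                          loop_index = NULL, runonce_index = NULL,
                          sweep_name = NULL, line = "Slow0", channel = NULL,
                          value = TRUE, protocol = NULL) {
  action <- match.arg(action)
  as_int <- function(x) if (is.null(x)) NULL else as.integer(x)
  structure(list(action = action, at_time = at_time,
                 after_sweep = as_int(after_sweep),
                 loop_index = as_int(loop_index),
                 runonce_index = as_int(runonce_index),
                 sweep_name = sweep_name, line = line,
                 channel = as_int(channel), value = value,
                 protocol = as_int(protocol)),
            class = "control_event")
}

ctrl_fired <- function(ctrl, env) {
  if (!is.null(ctrl$protocol) && ctrl$protocol != env$protocol_index)
    return(FALSE)
  t_ok <- is.null(ctrl$at_time) || env$clock >= ctrl$at_time - 1e-9
  s_ok <- is.null(ctrl$after_sweep) || env$sweep_i >= ctrl$after_sweep
  t_ok && s_ok
}

# ---- internal executor state ------------------------------------------------

new_exec_env <- function(rig, controls, seed = NULL) {
  env <- new.env(parent = emptyenv())
  env$rig <- rig
  env$clock <- 0
  env$sweep_i <- 0L
  env$sweeps <- list()
  env$waveforms <- list()
  env$perfusions <- list()
  env$valve_rows <- list()
  env$activations <- list()
  env$log <- character()
  env$warnings <- character()
  env$protocols_run <- character()
  env$n_link_events <- 0L
  env$line_channels <- stats::setNames(rep(0L, length(PERFUSION_LINES)),
                                       PERFUSION_LINES)
  env$override <- FALSE
  env$set_ch_to_last <- FALSE
  env$controls <- controls
  env$consumed <- rep(FALSE, length(controls))
  env$protocol_index <- 1L
  env$protocol_name <- ""
  env$script <- NULL
  env$loops_seen <- integer()
  env$running <- FALSE
  env$jitter_fun <- if (rig$slow_port_jitter_ms > 0 && !is.null(seed)) {
    rng <- local({ s <- seed; function() {
      s <<- (1103515245 * s + 12345) %% 2147483648
      s / 2147483648
    }})
    function() rng() * rig$slow_port_jitter_ms / 1000
  } else if (rig$slow_port_jitter_ms > 0) {
    function() stats::runif(1, 0, rig$slow_port_jitter_ms / 1000)
  } else {
    function() 0
  }
  env
}

log_line <- function(env, fmt, ...) {
  env$log <- c(env$log, sprintf(paste0("[%10.1f s] ", fmt), env$clock, ...))
}

warn_line <- function(env, fmt, ...) {
  env$warnings <- c(env$warnings, sprintf(fmt, ...))
}

# matching EndLoop/EndRunOnce position for each opener, plus static ids
index_blocks <- function(events) {
  n <- length(events)
  match_pos <- rep(NA_integer_, n)
  loop_id <- rep(NA_integer_, n)
  runonce_id <- rep(NA_integer_, n)
  stack <- integer()
  n_loop <- 0L
  n_ro <- 0L
  for (i in seq_len(n)) {
    k <- events[[i]]$kind
    if (k %in% c("Loop", "RunOnce")) {
      stack <- c(stack, i)
      if (k == "Loop") { n_loop <- n_loop + 1L; loop_id[i] <- n_loop }
      else { n_ro <- n_ro + 1L; runonce_id[i] <- n_ro }
    } else if (k %in% c("EndLoop", "EndRunOnce")) {
      if (length(stack) == 0L)
        stop("unbalanced nesting: stray ", k, call. = FALSE)
      match_pos[stack[length(stack)]] <- i
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced nesting: unclosed block", call. = FALSE)
  list(match_pos = match_pos, loop_id = loop_id, runonce_id = runonce_id)
}

# ---- event actions ----------------------------------------------------------

do_perfuse <- function(env, line, channel) {
  rig <- env$rig
  script <- env$script
  label <- solution_label(script, line, channel)
  cfg <- rig$controllers[[line]]
  if (is.null(cfg)) stop("no controller configured for line ", line,
                         call. = FALSE)
  suppressed <- isTRUE(env$override)
  event_time <- env$clock
  switch_time <- event_time
  from <- env$line_channels[[line]]
  if (!suppressed) {
    plan <- plan_switch(rig, line, from, channel)
    jit <- if (!is_fast_line(line)) env$jitter_fun() else 0
    if (nrow(plan)) {
      rows <- data.frame(time_s = event_time + jit + plan$time_s,
                         line = line, port = plan$port, kind = plan$kind,
                         bit = plan$bit, value = plan$value,
                         stringsAsFactors = FALSE)
      env$valve_rows[[length(env$valve_rows) + 1L]] <- rows
      switch_time <- event_time + jit + max(plan$time_s)
    }
    env$line_channels[[line]] <- channel
    if (channel > 0L)
      env$activations[[length(env$activations) + 1L]] <-
        data.frame(time_s = switch_time, line = line, channel = channel,
                   source = "perfuse", stringsAsFactors = FALSE)
  }
  env$perfusions[[length(env$perfusions) + 1L]] <-
    data.frame(time_s = event_time, switch_time_s = switch_time, line = line,
               from_channel = if (suppressed) NA_integer_ else from,
               to_channel = channel, label = label,
               scheme = rig$scheme[[line]] %||% "standard",
               suppressed = suppressed, protocol = env$protocol_index,
               stringsAsFactors = FALSE)
  log_line(env, "Perfuse %s Ch%d %s%s", line, channel, label,
           if (suppressed) " [suppressed: override active]" else "")
  invisible(env)
}

do_sweep <- function(env, name, manual = FALSE) {
  rig <- env$rig
  sd <- rig$sweep_defs[[name]]
  if (is.null(sd)) stop("sweep '", name, "' not defined on this rig",
                        call. = FALSE)
  ov <- env$script$sweep_overrides[[name]]
  if (!is.null(ov)) {
    if (is.null(sd$ic1_epochs))
      stop("script overrides IC1 epochs of '", name,
           "' but the rig sweep has none", call. = FALSE)
    sd$ic1_epochs$amplitude <- ov
  }
  start <- env$clock
  env$sweep_i <- env$sweep_i + 1L
  idx <- env$sweep_i
  ic1_cfg <- NULL
  if (!is.null(sd$ic1_epochs)) {
    ic1_line <- if (!is.null(rig$controllers$Fast0)) "Fast0" else "Fast1"
    ic1_cfg <- rig$controllers[[ic1_line]]
    if (is.null(ic1_cfg))
      stop("sweep ", name, " has IC1 perfusion epochs but no fast line is ",
           "configured", call. = FALSE)
  }
  w <- render_sweep(sd, state = as.list(env$line_channels), cfg = ic1_cfg)
  if (env$record_waveforms) env$waveforms[[idx]] <- w
  if (!is.null(w$ic1_resolved)) {
    ep <- w$ic1_resolved
    ep_new <- ep[!ep$sentinel & ep$channel > 0L, , drop = FALSE]
    if (nrow(ep_new)) {
      env$activations[[length(env$activations) + 1L]] <-
        data.frame(time_s = start + ep_new$onset_ms / 1000, line = ic1_cfg$line,
                   channel = ep_new$channel, source = "epoch",
                   stringsAsFactors = FALSE)
      env$valve_rows[[length(env$valve_rows) + 1L]] <-
        data.frame(time_s = start + ep_new$onset_ms / 1000,
                   line = ic1_cfg$line, port = "IC1", kind = "analog",
                   bit = NA_integer_, value = ep_new$volts,
                   stringsAsFactors = FALSE)
    }
  }
  env$sweeps[[idx]] <- data.frame(
    index = idx, start_time_s = start, name = name,
    duration_s = sd$duration_ms / 1000, manual = manual,
    protocol = env$protocol_index, stringsAsFactors = FALSE)
  log_line(env, "Sweep %s%s", name, if (manual) " [manual]" else "")
  env$clock <- start + sd$duration_ms / 1000 + env$rig$inter_sweep_interval_s
  invisible(env)
}

process_controls <- function(env) {
  for (j in seq_along(env$controls)) {
    if (env$consumed[j]) next
    ctrl <- env$controls[[j]]
    if (!ctrl$action %in% c("single_sweep", "set_override", "manual_apply",
                            "set_ch_to_last_perfuse")) next
    if (!ctrl_fired(ctrl, env)) next
    env$consumed[j] <- TRUE
    switch(ctrl$action,
      single_sweep = do_sweep(env, ctrl$sweep_name, manual = TRUE),
      set_override = {
        if (is.null(ctrl$channel)) {
          env$override <- FALSE
        } else {
          env$override <- TRUE
          apply_manual(env, ctrl$line, ctrl$channel)
        }
      },
      manual_apply = {
        if (env$running && !env$override) {
          warn_line(env,
            "manual Apply of %s Ch%d at t=%.1f s rejected: protocol running without Override",
            ctrl$line, ctrl$channel, env$clock)
        } else {
          apply_manual(env, ctrl$line, ctrl$channel)
        }
      },
      set_ch_to_last_perfuse = env$set_ch_to_last <- isTRUE(ctrl$value))
  }
  invisible(env)
}

# a manual channel change bypasses the script but uses the same plumbing
apply_manual <- function(env, line, channel) {
  rig <- env$rig
  from <- env$line_channels[[line]]
  plan <- plan_switch(rig, line, from, channel)
  if (nrow(plan)) {
    env$valve_rows[[length(env$valve_rows) + 1L]] <-
      data.frame(time_s = env$clock + plan$time_s, line = line,
                 port = plan$port, kind = plan$kind, bit = plan$bit,
                 value = plan$value, stringsAsFactors = FALSE)
  }
  env$line_channels[[line]] <- channel
  if (channel > 0L)
    env$activations[[length(env$activations) + 1L]] <-
      data.frame(time_s = env$clock, line = line, channel = channel,
                 source = "manual", stringsAsFactors = FALSE)
  invisible(env)
}

uncheck_fired <- function(env, loop_id) {
  for (j in seq_along(env$controls)) {
    ctrl <- env$controls[[j]]
    if (ctrl$action == "uncheck_loop" && isTRUE(ctrl$loop_index == loop_id) &&
        ctrl_fired(ctrl, env)) return(TRUE)
  }
  FALSE
}

consume_runonce_check <- function(env, ro_id) {
  for (j in seq_along(env$controls)) {
    if (env$consumed[j]) next
    ctrl <- env$controls[[j]]
    if (ctrl$action == "check_runonce" &&
        isTRUE(ctrl$runonce_index == ro_id) && ctrl_fired(ctrl, env)) {
      env$consumed[j] <- TRUE
      return(TRUE)
    }
  }
  FALSE
}

exec_range <- function(env, events, blocks, lo, hi) {
  i <- lo
  while (i <= hi) {
    ev <- events[[i]]
    switch(ev$kind,
      Loop = {
        m <- blocks$match_pos[i]
        id <- blocks$loop_id[i]
        env$loops_seen <- union(env$loops_seen, id)
        if (ev$continuous) {
          # exit is tested at the end of each iteration: an uncheck arriving
          # mid-iteration lets the current iteration finish first
          repeat {
            exec_range(env, events, blocks, i + 1L, m - 1L)
            process_controls(env)
            if (uncheck_fired(env, id)) break
          }
        } else {
          for (k in seq_len(ev$loop_count)) {
            exec_range(env, events, blocks, i + 1L, m - 1L)
            process_controls(env)
          }
        }
        i <- m + 1L
      },
      RunOnce = {
        m <- blocks$match_pos[i]
        if (consume_runonce_check(env, blocks$runonce_id[i]))
          exec_range(env, events, blocks, i + 1L, m - 1L)
        i <- m + 1L
      },
      Sweep = { do_sweep(env, ev$sweep_name); process_controls(env); i <- i + 1L },
      Delay = {
        env$clock <- env$clock + ev$delay_s
        process_controls(env)
        i <- i + 1L
      },
      Perfuse = { do_perfuse(env, ev$line, ev$channel); process_controls(env)
                  i <- i + 1L },
      EndLoop = ,
      EndRunOnce = i <- i + 1L,
      {
        warn_line(env, "skipping unsupported event '%s'", ev$kind)
        i <- i + 1L
      })
  }
  invisible(env)
}

exec_script <- function(env, script) {
  env$script <- script
  env$protocol_name <- script$name
  env$protocols_run <- c(env$protocols_run, script$name)
  env$loops_seen <- integer()
  blocks <- index_blocks(script$events)
  env$running <- TRUE
  process_controls(env)
  exec_range(env, script$events, blocks, 1L, length(script$events))
  env$running <- FALSE
  # controls aimed at loops this protocol never reached
  all_loops <- stats::na.omit(blocks$loop_id)
  for (ctrl in env$controls) {
    if (ctrl$action == "uncheck_loop" &&
        (is.null(ctrl$protocol) || ctrl$protocol == env$protocol_index) &&
        !is.null(ctrl$loop_index) && ctrl$loop_index %in% all_loops &&
        !ctrl$loop_index %in% env$loops_seen) {
      warn_line(env, "control event targets loop %d of '%s', never reached",
                ctrl$loop_index, script$name)
    }
  }
  invisible(env)
}

finalize_record <- function(env) {
  if (!env$set_ch_to_last) {
    for (line in names(env$line_channels)) {
      if (env$line_channels[[line]] > 0L) do_perfuse(env, line, 0L)
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  rec <- list(
    sweeps = bind(env$sweeps, data.frame(
      index = integer(), start_time_s = numeric(), name = character(),
      duration_s = numeric(), manual = logical(), protocol = integer())),
    waveforms = env$waveforms,
    perfusions = bind(env$perfusions, data.frame(
      time_s = numeric(), switch_time_s = numeric(), line = character(),
      from_channel = integer(), to_channel = integer(), label = character(),
      scheme = character(), suppressed = logical(), protocol = integer())),
    valve_timeline = {
      v <- bind(env$valve_rows, data.frame(
        time_s = numeric(), line = character(), port = character(),
        kind = character(), bit = integer(), value = numeric()))
      v[order(v$time_s), , drop = FALSE]
    },
    activations = bind(env$activations, data.frame(
      time_s = numeric(), line = character(), channel = integer(),
      source = character())),
    log = env$log,
    warnings = env$warnings,
    protocols_run = env$protocols_run,
    n_link_events = env$n_link_events,
    line_channels = env$line_channels,
    end_time_s = env$clock)
  rownames(rec$valve_timeline) <- NULL
  class(rec) <- "experiment_record"
  rec
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf(paste0("<experiment_record> %d sweep(s), %d perfusion event(s), ",
                     "%d valve action(s), %.1f s simulated\n"),
              nrow(x$sweeps), nrow(x$perfusions), nrow(x$valve_timeline),
              x$end_time_s))
  cat(sprintf("  protocols: %s\n", paste(x$protocols_run, collapse = " -> ")))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings),
                x$warnings[1L]))
  invisible(x)
}

# ---- public entry points ----------------------------------------------------

#' Execute a protocol script on the virtual rig
#'
#' Runs the script's events in order under simulated wall time: counted
#' loops run exactly their count, continuous loops repeat until their
#' uncheck control event fires (tested at the end of each iteration),
#' Perfuse events emit their valve switch plans between sweeps, RunOnce
#' bodies run once per check, and Override suppresses scripted perfusion
#' changes. Unless a `set_ch_to_last_perfuse` control set the keep flag, all
#' perfusion lines are switched off when the protocol ends.
#'
#' @param script a [protocol_script()] (validate with [validate_protocol()]
#'   first; structural problems raise errors here).
#' @param rig a [rig_config()].
#' @param controls list of [control_event()]s (simulated operator actions).
#' @param inter_sweep_interval_s overrides the rig's sweep pacing.
#' @param record_waveforms keep every rendered sweep in the record (turn off
#'   for very long runs).
#' @param seed seed for the slow-port latency jitter (only used when the rig
#'   sets `slow_port_jitter_ms > 0`). Identical inputs and seed give an
#'   identical record.
#' @return an `experiment_record`: executed sweeps, merged valve timeline,
#'   perfusion events, channel activations, log lines and final line states.
#' @export
run_protocol <- function(script, rig, controls = list(),
                         inter_sweep_interval_s = NULL,
                         record_waveforms = TRUE, seed = NULL) {
  stopifnot(inherits(script, "protocol_script"), inherits(rig, "rig_config"))
  if (!is.null(inter_sweep_interval_s))
    rig$inter_sweep_interval_s <- inter_sweep_interval_s
  env <- new_exec_env(rig, controls, seed)
  env$record_waveforms <- record_waveforms
  exec_script(env, script)
  finalize_record(env)
}

#' Execute a chain of linked protocol scripts
#'
#' Protocols run back to back under one monotone clock, as when a finished
#' protocol loads its successor. Protocol k+1 starts automatically when its
#' autostart flag is set; otherwise it waits for a `start_protocol` control
#' event (and the run ends if none is supplied). Loads and starts are logged.
#'
#' @param scripts list of [protocol_script()]s in run order.
#' @param rig a [rig_config()].
#' @param controls list of [control_event()]s; use the `protocol` field to
#'   scope a control to one protocol in the chain.
#' @param autostart logical vector: does protocol k start automatically?
#'   Entry 1 is ignored (the operator starts the first protocol). Defaults
#'   to each predecessor's `[link]` autostart flag.
#' @param record_waveforms,seed as in [run_protocol()].
#' @return an `experiment_record` spanning every protocol that ran.
#' @export
run_linked <- function(scripts, rig, controls = list(), autostart = NULL,
                       record_waveforms = TRUE, seed = NULL) {
  stopifnot(length(scripts) >= 1L,
            all(vapply(scripts, inherits, TRUE, "protocol_script")))
  if (is.null(autostart)) {
    autostart <- c(TRUE, vapply(seq_along(scripts)[-1L], function(k) {
      lk <- scripts[[k - 1L]]$link
      !is.null(lk) && isTRUE(lk$autostart)
    }, TRUE))
  }
  stopifnot(length(autostart) == length(scripts))
  env <- new_exec_env(rig, controls, seed)
  env$record_waveforms <- record_waveforms
  for (k in seq_along(scripts)) {
    env$protocol_index <- k
    if (k > 1L) {
      log_line(env, "Loaded protocol '%s'", scripts[[k]]$name)
      env$n_link_events <- env$n_link_events + 1L
      if (!autostart[k]) {
        starts <- Filter(function(c) c$action == "start_protocol" &&
                           isTRUE(c$protocol == k), env$controls)
        if (length(starts) == 0L) {
          warn_line(env,
            "protocol %d ('%s') has no autostart and no start control; run ends",
            k, scripts[[k]]$name)
          break
        }
        t_start <- starts[[1L]]$at_time %||% env$clock
        env$clock <- max(env$clock, t_start)
      }
    }
    log_line(env, "Started protocol '%s'", scripts[[k]]$name)
    env$n_link_events <- env$n_link_events + 1L
    exec_script(env, scripts[[k]])
  }
  finalize_record(env)
}

#' Load a protocol file and the chain it links to
#'
#' Follows each script's `[link]` block (paths resolved relative to the
#' linking file) until a script with no link, a missing file, or `max`
#' protocols.
#'
#' @param path path of the first `.proto` file.
#' @param max safety bound on chain length.
#' @return list of [protocol_script()]s; if a linked file is missing, the
#'   chain up to it is returned with attribute `missing` naming the file.
#' @export
load_protocol_chain <- function(path, max = 50L) {
  scripts <- list()
  cur <- path
  repeat {
    if (!file.exists(cur)) {
      attr(scripts, "missing") <- cur
      break
    }
    s <- read_protocol(cur)
    scripts <- c(scripts, list(s))
    if (is.null(s$link) || length(scripts) >= max) break
    cur <- file.path(dirname(cur), s$link$next_protocol)
  }
  scripts
}

#' Run a protocol file, following its link chain
#'
#' @param path first `.proto` file.
#' @param rig a [rig_config()].
#' @param ... passed to [run_linked()].
#' @return an `experiment_record`. A missing linked file stops the run with
#'   a logged error.
#' @export
run_linked_files <- function(path, rig, ...) {
  scripts <- load_protocol_chain(path)
  rec <- run_linked(scripts, rig, ...)
  missing <- attr(scripts, "missing")
  if (!is.null(missing)) {
    rec$log <- c(rec$log,
                 sprintf("[%10.1f s] ERROR: linked protocol '%s' not found; run stopped",
                         rec$end_time_s, missing))
    rec$n_link_events <- rec$n_link_events + 1L
    rec$warnings <- c(rec$warnings,
                      sprintf("linked protocol '%s' not found", missing))
  }
  rec
}

#' The experimental log as text
#'
#' One line per perfusion change (time, line, channel, solution label), per
#' sweep (time, sweep name) and per protocol load/start; formatting is
#' deterministic.
#'
#' @param record an `experiment_record`.
#' @return character scalar.
#' @export
emit_log <- function(record) paste(record$log, collapse = "\n")

#' Derive a recirculation valve timeline from a record
#'
#' A second slow line can route chamber waste either back to the source
#' reservoir or to the waste container, depending on which solution is
#' flowing. Given a policy per channel, the recirculation line mirrors each
#' (non-suppressed) channel change on the perfusion line.
#'
#' @param record an `experiment_record`.
#' @param policy named character vector mapping channel numbers (as names)
#'   to `"recirculate"` or `"waste"`; channels not named default to waste.
#' @param line the perfusion line to mirror (default `"Slow0"`).
#' @param recirc_line the line driving the recirculation valve.
#' @return data frame `time_s`, `channel`, `action`, `value` (1 =
#'   recirculation path engaged) -- the recirculation line's valve timeline.
#' @export
run_recirculation_policy <- function(record, policy = character(),
                                     line = "Slow0", recirc_line = "Slow1") {
  p <- record$perfusions
  p <- p[p$line == line & !p$suppressed, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(time_s = numeric(), channel = integer(),
                      action = character(), value = numeric(),
                      line = character()))
  act <- vapply(p$to_channel, function(ch) {
    a <- unname(policy[as.character(ch)])
    if (length(a) != 1L || is.na(a)) "waste" else a
  }, "")
  data.frame(time_s = p$switch_time_s, channel = p$to_channel, action = act,
             value = as.numeric(act == "recirculate"), line = recirc_line,
             stringsAsFactors = FALSE)
}

#' Channel switches of one line, shaped for transport simulation
#'
#' @param record an `experiment_record`.
#' @param line perfusion line id.
#' @return data frame `time_s` (chamber-valve switch time), `to_channel`,
#'   `scheme`, `solute` (solution label) -- the input [advance_transport()]
#'   expects.
#' @export
record_switches <- function(record, line = "Slow0") {
  p <- record$perfusions
  p <- p[p$line == line & !p$suppressed, , drop = FALSE]
  data.frame(time_s = p$switch_time_s, to_channel = p$to_channel,
             scheme = p$scheme, solute = p$label, stringsAsFactors = FALSE)
}

#' Gap-free trace of a line's commanded channel
#'
#' The continuous-acquisition stand-in: the channel (and, for analog
#' controllers, the command voltage) in force at each sample time.
#'
#' @param record an `experiment_record`.
#' @param rig the rig the record was produced on.
#' @param line perfusion line id.
#' @param dt_s sample interval.
#' @return data frame `time_s`, `channel`, `volts` (NA for non-analog
#'   controllers).
#' @export
continuous_channel_trace <- function(record, rig, line = "Slow0", dt_s = 1) {
  sw <- record_switches(record, line)
  times <- unique(c(seq(0, record$end_time_s, by = dt_s), record$end_time_s))
  ch <- integer(length(times))
  cur <- 0L
  j <- 1L
  for (k in seq_along(times)) {
    while (j <= nrow(sw) && sw$time_s[j] <= times[k] + 1e-9) {
      cur <- sw$to_channel[j]
      j <- j + 1L
    }
    ch[k] <- cur
  }
  cfg <- rig$controllers[[line]]
  volts <- if (!is.null(cfg) && cfg$mode == "analog")
    ch * cfg$volts_per_channel else NA_real_
  data.frame(time_s = times, channel = ch, volts = volts)
}
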