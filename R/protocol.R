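# The protocol-script event language: a line-oriented text dialect with one
# event per line between MainProtocol and EndProtocol, an optional [labels]
# block naming (line, channel) solutions, and an optional [link] block
# chaining to a next protocol file.

SWEEP_NAMES <- c("P0sweep", "P1sweep", "T0sweep", "T1sweep")
CONTINUOUS_LOOP_COUNT <- 99999L  # the "loop continuously" sentinel count

# ---- event constructors -----------------------------------------------------

#' Protocol event constructors
#'
#' Build protocol events programmatically (the same structures produced by
#' [parse_protocol()]). A `Loop` with `continuous = TRUE` carries the
#' sentinel count 99999 and on execution repeats until its checkbox is
#' "unchecked" by a control event; a counted loop runs exactly `count` times.
#'
#' @param count loop iteration count, 1 to 99999.
#' @param continuous logical; continuous (checkbox-style) loop.
#' @param seconds delay duration in seconds.
#' @param name sweep name (`"P0sweep"`, `"P1sweep"`, `"T0sweep"`, `"T1sweep"`).
#' @param line perfusion line id.
#' @param channel perfusion channel number (>= 0).
#' @return a `protocol_event` list.
#' @name protocol_events
NULL

new_event <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "protocol_event")
}

#' @rdname protocol_events
#' @export
ev_loop <- function(count, continuous = FALSE) {
  count <- as.integer(count)
  if (is.na(count) || count < 1L || count > 99999L)
    stop("loop count must be in [1, 99999]", call. = FALSE)
  if (continuous) count <- CONTINUOUS_LOOP_COUNT
  new_event("Loop", loop_count = count, continuous = isTRUE(continuous))
}

#' @rdname protocol_events
#' @export
ev_endloop <- function() new_event("EndLoop")

#' @rdname protocol_events
#' @export
ev_delay <- function(seconds) {
  stopifnot(seconds >= 0)
  new_event("Delay", delay_s = as.numeric(seconds))
}

#' @rdname protocol_events
#' @export
ev_sweep <- function(name) {
  name <- match.arg(name, SWEEP_NAMES)
  new_event("Sweep", sweep_name = name)
}

#' @rdname protocol_events
#' @export
ev_perfuse <- function(line, channel) {
  line <- match.arg(line, PERFUSION_LINES)
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 0L)
    stop("Perfuse channel must be an integer >= 0", call. = FALSE)
  new_event("Perfuse", line = line, channel = channel)
}

#' @rdname protocol_events
#' @export
ev_runonce <- function() new_event("RunOnce")

#' @rdname protocol_events
#' @export
ev_endrunonce <- function() new_event("EndRunOnce")

#' @export
print.protocol_event <- function(x, ...) {
  cat("<protocol_event>", event_to_line(x), "\n")
  invisible(x)
}

# ---- script container -------------------------------------------------------

#' Construct a protocol script
#'
#' @param events list of protocol events (see [protocol_events]).
#' @param labels data frame with columns `line`, `channel`, `label` mapping
#'   perfusion channels to solution names, or `NULL`.
#' @param link `NULL`, or a list with `next_protocol` (path of the protocol
#'   file to load when this one finishes) and `autostart` (logical).
#' @param sweep_overrides named list: per-sweep IC1 epoch amplitudes (length-3
#'   numeric, channel units or -1 sentinel) that this script applies on top
#'   of the rig's sweep definitions -- each protocol file can thus deliver
#'   its own within-sweep perfusion channels.
#' @param name optional script name (defaults to the source file name).
#' @return an object of class `protocol_script`.
#' @export
protocol_script <- function(events = list(), labels = NULL, link = NULL,
                            sweep_overrides = list(), name = "protocol") {
  stopifnot(all(vapply(events, inherits, TRUE, "protocol_event")))
  if (is.null(labels)) {
    labels <- data.frame(line = character(), channel = integer(),
                         label = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("line", "channel", "label") %in% names(labels)))
  if (!is.null(link)) {
    stopifnot(is.list(link), !is.null(link$next_protocol))
    link$autostart <- isTRUE(link$autostart)
    if (link$autostart && !nzchar(link$next_protocol))
      stop("link path must be nonempty when autostart is set", call. = FALSE)
  }
  if (length(sweep_overrides)) {
    stopifnot(all(names(sweep_overrides) %in% SWEEP_NAMES),
              all(vapply(sweep_overrides, length, 0L) == 3L))
  }
  structure(list(events = events, labels = labels, link = link,
                 sweep_overrides = sweep_overrides, name = name),
            class = "protocol_script")
}

#' @export
print.protocol_script <- function(x, ...) {
  cat(sprintf("<protocol_script> '%s': %d event(s), %d label(s)%s\n",
              x$name, length(x$events), nrow(x$labels),
              if (!is.null(x$link))
                sprintf(", links to '%s'%s", x$link$next_protocol,
                        if (x$link$autostart) " (autostart)" else "")
              else ""))
  cat(serialize_protocol(x), sep = "\n")
  invisible(x)
}

#' Solution label for a (line, channel) pair
#'
#' Falls back to the generated default `"Ch<n>"` when no label was entered.
#'
#' @param script a `protocol_script`.
#' @param line perfusion line id.
#' @param channel channel number.
#' @return character label.
#' @export
solution_label <- function(script, line, channel) {
  hit <- script$labels$line == line & script$labels$channel == channel
  if (any(hit)) script$labels$label[which(hit)[1L]] else paste0("Ch", channel)
}

# ---- parsing ----------------------------------------------------------------

strip_comment <- function(line) sub("#.*$", "", line)

parse_event_line <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1L]]
  err <- function(msg) stop(sprintf("line %d: %s ('%s')", lineno, msg,
                                    trimws(line)), call. = FALSE)
  kw <- toks[1L]
  switch(kw,
    Loop = {
      if (length(toks) < 2L) err("Loop requires a count")
      n <- suppressWarnings(as.integer(toks[2L]))
      if (is.na(n)) err("Loop count is not an integer")
      if (n < 1L || n > 99999L) err("Loop count out of [1, 99999]")
      cont <- length(toks) >= 3L && toks[3L] == "continuous"
      if (length(toks) > 2L + cont) err("trailing tokens after Loop")
      ev <- new_event("Loop", loop_count = n, continuous = cont)
      if (cont && n != CONTINUOUS_LOOP_COUNT) ev$loop_count <- CONTINUOUS_LOOP_COUNT
      ev
    },
    EndLoop = new_event("EndLoop"),
    Delay = {
      if (length(toks) != 2L) err("Delay requires one duration (seconds)")
      s <- suppressWarnings(as.numeric(toks[2L]))
      if (is.na(s) || s < 0) err("Delay duration is not a non-negative number")
      new_event("Delay", delay_s = s)
    },
    Perfuse = {
      if (length(toks) != 3L) err("Perfuse requires a line and a channel")
      if (!toks[2L] %in% PERFUSION_LINES)
        err(paste0("unknown perfusion line '", toks[2L], "'"))
      ch <- suppressWarnings(as.integer(toks[3L]))
      if (is.na(ch) || ch < 0L) err("Perfuse channel must be an integer >= 0")
      new_event("Perfuse", line = toks[2L], channel = ch)
    },
    RunOnce = new_event("RunOnce"),
    EndRunOnce = new_event("EndRunOnce"),
    Run = new_event("Run"),
    ElseRun = new_event("ElseRun"),
    {
      if (kw %in% SWEEP_NAMES) {
        if (length(toks) != 1L) err("trailing tokens after sweep name")
        new_event("Sweep", sweep_name = kw)
      } else {
        err(paste0("unknown event '", kw, "'"))
      }
    })
}

#' Parse protocol-script text
#'
#' The dialect is line oriented: one event per line between `MainProtocol`
#' and `EndProtocol`, `#` comments, optional indentation, then optional
#' `[labels]` (`<line> <channel> = <solution name>`) and `[link]`
#' (`next = <file>`, `autostart = true|false`) blocks.
#'
#' @param text a single string (with embedded newlines) or a character
#'   vector of lines.
#' @param strict when `TRUE` (default) unbalanced `Loop`/`EndLoop` or
#'   `RunOnce`/`EndRunOnce` nesting is an error; when `FALSE` it is left for
#'   [validate_protocol()] to report.
#' @param name script name recorded in the result.
#' @return a [protocol_script()]. Event order is preserved exactly.
#' @examples
#' parse_protocol("MainProtocol
#'   Loop 99999 continuous
#'     P0sweep
#'   EndLoop
#' EndProtocol")
#' @export
parse_protocol <- function(text, strict = TRUE, name = "protocol") {
  stopifnot(length(text) >= 1L)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- lines
  lines <- trimws(vapply(lines, strip_comment, ""))

  nonblank <- which(nzchar(lines))
  if (length(nonblank) == 0L) stop("empty protocol text", call. = FALSE)

  i_main <- nonblank[lines[nonblank] == "MainProtocol"]
  i_end <- nonblank[lines[nonblank] == "EndProtocol"]
  if (length(i_main) != 1L)
    stop("protocol must contain exactly one MainProtocol line", call. = FALSE)
  if (length(i_end) != 1L || i_end < i_main)
    stop("protocol must contain exactly one EndProtocol line after MainProtocol",
         call. = FALSE)
  if (any(nonblank < i_main))
    stop(sprintf("line %d: content before MainProtocol", min(nonblank)),
         call. = FALSE)

  events <- list()
  depth_stack <- character()
  for (i in setdiff(which(nzchar(lines)), c(i_main, i_end))) {
    if (i > i_end) break
    ev <- parse_event_line(lines[i], i)
    if (ev$kind %in% c("Loop", "RunOnce")) depth_stack <- c(depth_stack, ev$kind)
    if (ev$kind %in% c("EndLoop", "EndRunOnce")) {
      want <- if (ev$kind == "EndLoop") "Loop" else "RunOnce"
      if (length(depth_stack) == 0L || depth_stack[length(depth_stack)] != want) {
        if (strict)
          stop(sprintf("line %d: %s without matching %s", i, ev$kind, want),
               call. = FALSE)
      } else {
        depth_stack <- depth_stack[-length(depth_stack)]
      }
    }
    events <- c(events, list(ev))
  }
  if (strict && length(depth_stack) > 0L)
    stop("unbalanced nesting: unclosed ",
         paste(depth_stack, collapse = ", "), call. = FALSE)

  # trailing [labels] / [link] / [sweeps] blocks
  labels <- NULL
  link <- NULL
  sweep_overrides <- list()
  block <- ""
  label_rows <- list()
  for (i in which(nzchar(lines))) {
    if (i <= i_end) next
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      block <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!block %in% c("labels", "link", "sweeps"))
        stop(sprintf("line %d: unknown block [%s]", i, block), call. = FALSE)
      next
    }
    if (block == "labels") {
      # keep the raw line so label text may contain '#'-free punctuation
      m <- regmatches(ln, regexec("^(\\S+)\\s+(\\d+)\\s*=\\s*(.*)$", ln))[[1L]]
      if (length(m) != 4L || !m[2L] %in% PERFUSION_LINES)
        stop(sprintf("line %d: bad label line (expected '<line> <ch> = <name>')",
                     i), call. = FALSE)
      label_rows[[length(label_rows) + 1L]] <-
        data.frame(line = m[2L], channel = as.integer(m[3L]),
                   label = trimws(m[4L]), stringsAsFactors = FALSE)
    } else if (block == "link") {
      m <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(.*)$", ln))[[1L]]
      if (length(m) != 3L)
        stop(sprintf("line %d: bad link line", i), call. = FALSE)
      if (is.null(link)) link <- list(next_protocol = "", autostart = FALSE)
      if (m[2L] == "next") link$next_protocol <- trimws(m[3L])
      else if (m[2L] == "autostart") link$autostart <- tolower(trimws(m[3L])) %in%
          c("true", "yes", "1")
      else stop(sprintf("line %d: unknown link key '%s'", i, m[2L]),
                call. = FALSE)
    } else if (block == "sweeps") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s+ic1\\s*=\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)$", ln))[[1L]]
      if (length(m) != 5L || !m[2L] %in% SWEEP_NAMES)
        stop(sprintf(
          "line %d: bad sweep override (expected '<sweep> ic1 = a b c')", i),
          call. = FALSE)
      amps <- suppressWarnings(as.numeric(m[3:5]))
      if (anyNA(amps))
        stop(sprintf("line %d: non-numeric IC1 amplitude", i), call. = FALSE)
      sweep_overrides[[m[2L]]] <- amps
    } else {
      stop(sprintf("line %d: content after EndProtocol outside a block", i),
           call. = FALSE)
    }
  }
  if (length(label_rows)) labels <- do.call(rbind, label_rows)
  if (!is.null(link) && !nzchar(link$next_protocol)) {
    if (link$autostart)
      stop("[link] block sets autostart but no next protocol", call. = FALSE)
    link <- NULL
  }
  protocol_script(events, labels, link, sweep_overrides, name = name)
}

#' Read a protocol script from a `.proto` file
#' @param path file path.
#' @param ... passed to [parse_protocol()].
#' @return a [protocol_script()] named after the file.
#' @export
read_protocol <- function(path, ...) {
  parse_protocol(readLines(path, warn = FALSE), name = basename(path), ...)
}

# ---- serialization ----------------------------------------------------------

event_to_line <- function(ev, script = NULL) {
  switch(ev$kind,
    Loop = if (ev$continuous) sprintf("Loop %d continuous", CONTINUOUS_LOOP_COUNT)
           else sprintf("Loop %d", ev$loop_count),
    EndLoop = "EndLoop",
    Delay = sprintf("Delay %.10g", ev$delay_s),
    Sweep = ev$sweep_name,
    Perfuse = {
      base <- sprintf("Perfuse %s %d", ev$line, ev$channel)
      if (!is.null(script)) {
        lbl <- solution_label(script, ev$line, ev$channel)
        if (lbl != paste0("Ch", ev$channel)) base <- paste0(base, "  # ", lbl)
      }
      base
    },
    RunOnce = "RunOnce",
    EndRunOnce = "EndRunOnce",
    ev$kind)
}

#' Serialize a protocol script to its text form
#'
#' Produces the canonical dialect: nested events indented two spaces per
#' level, solution labels echoed as comments beside their Perfuse events and
#' recorded in a `[labels]` block, and the link plan in a `[link]` block.
#' `parse_protocol(serialize_protocol(s))` is structurally identical to `s`.
#'
#' @param script a [protocol_script()].
#' @return character scalar (the script text).
#' @export
serialize_protocol <- function(script) {
  out <- "MainProtocol"
  depth <- 1L
  for (ev in script$events) {
    if (ev$kind %in% c("EndLoop", "EndRunOnce")) depth <- max(1L, depth - 1L)
    out <- c(out, paste0(strrep("  ", depth), event_to_line(ev, script)))
    if (ev$kind %in% c("Loop", "RunOnce")) depth <- depth + 1L
  }
  out <- c(out, "EndProtocol")
  if (nrow(script$labels)) {
    out <- c(out, "", "[labels]",
             sprintf("%s %d = %s", script$labels$line, script$labels$channel,
                     script$labels$label))
  }
  if (length(script$sweep_overrides)) {
    out <- c(out, "", "[sweeps]",
             vapply(names(script$sweep_overrides), function(nm)
               sprintf("%s ic1 = %s", nm,
                       paste(format(script$sweep_overrides[[nm]]),
                             collapse = " ")), ""))
  }
  if (!is.null(script$link)) {
    out <- c(out, "", "[link]",
             sprintf("next = %s", script$link$next_protocol),
             sprintf("autostart = %s",
                     if (script$link$autostart) "true" else "false"))
  }
  paste(out, collapse = "\n")
}

#' Write a protocol script to a `.proto` file
#' @param script a [protocol_script()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(script, path) {
  writeLines(serialize_protocol(script), path)
  invisible(path)
}

# ---- validation -------------------------------------------------------------

#' Validate a protocol script against a rig configuration
#'
#' Checks (returning issues rather than raising): balanced `Loop`/`EndLoop`
#' and `RunOnce`/`EndRunOnce` nesting, loop counts within `[1, 99999]`,
#' every Perfuse channel within its line's controller range (and the line
#' configured at all), every referenced sweep defined on the rig, link
#' consistency, and `Run`/`ElseRun` events (parsed but unsupported).
#'
#' @param script a [protocol_script()].
#' @param rig a [rig_config()].
#' @return character vector of issues; empty when the script is valid.
#' @export
validate_protocol <- function(script, rig) {
  issues <- character()
  depth_stack <- character()
  for (ev in script$events) {
    switch(ev$kind,
      Loop = {
        depth_stack <- c(depth_stack, "Loop")
        if (ev$loop_count < 1L || ev$loop_count > 99999L)
          issues <- c(issues, sprintf("Loop count %d out of [1, 99999]",
                                      ev$loop_count))
      },
      RunOnce = depth_stack <- c(depth_stack, "RunOnce"),
      EndLoop = ,
      EndRunOnce = {
        want <- if (ev$kind == "EndLoop") "Loop" else "RunOnce"
        if (length(depth_stack) && depth_stack[length(depth_stack)] == want)
          depth_stack <- depth_stack[-length(depth_stack)]
        else issues <- c(issues, sprintf("%s without matching %s",
                                         ev$kind, want))
      },
      Sweep = {
        if (!ev$sweep_name %in% names(rig$sweep_defs))
          issues <- c(issues, sprintf("sweep '%s' not defined on this rig",
                                      ev$sweep_name))
      },
      Perfuse = {
        cfg <- rig$controllers[[ev$line]]
        if (is.null(cfg))
          issues <- c(issues, sprintf("no controller configured for line %s",
                                      ev$line))
        else if (ev$channel > cfg$n_channels)
          issues <- c(issues, sprintf(
            "Perfuse %s channel %d exceeds the controller's %d channels",
            ev$line, ev$channel, cfg$n_channels))
      },
      Run = ,
      ElseRun = issues <- c(issues, sprintf("unsupported event '%s'", ev$kind)),
      Delay = NULL)
  }
  if (length(depth_stack))
    issues <- c(issues, sprintf("unclosed %s block(s): %s",
                                length(depth_stack),
                                paste(depth_stack, collapse = ", ")))
  if (!is.null(script$link) && script$link$autostart &&
      !nzchar(script$link$next_protocol))
    issues <- c(issues, "link autostart set but next protocol path is empty")
  fast_cfg <- rig$controllers$Fast0 %||% rig$controllers$Fast1
  for (nm in names(script$sweep_overrides)) {
    if (!nm %in% names(rig$sweep_defs)) {
      issues <- c(issues, sprintf("sweep override for undefined sweep '%s'", nm))
    } else if (!is.null(fast_cfg)) {
      amps <- script$sweep_overrides[[nm]]
      bad <- amps[amps != -1 & (amps < 0 | amps > fast_cfg$n_channels)]
      if (length(bad))
        issues <- c(issues, sprintf(
          "sweep '%s' IC1 amplitude %s selects no channel on the %d-channel fast controller",
          nm, paste(bad, collapse = ","), fast_cfg$n_channels))
    }
  }
  issues
}
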