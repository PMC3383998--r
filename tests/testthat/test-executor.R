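# Discrete-event execution: loops, controls, perfusion sequencing, linking,
# logging.

uncheck1 <- function(after = 3) {
  list(control_event("uncheck_loop", after_sweep = after, loop_index = 1))
}

test_that("the perfusion LTP script executes in the documented order", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                      controls = uncheck1(3))
  # interleave perfusions and sweeps into one ordered symbol sequence;
  # a perfusion sharing a timestamp with a sweep happened just before it
  ev <- rbind(
    data.frame(t = rec$sweeps$start_time_s, pr = 1,
               sym = sub("sweep", "", rec$sweeps$name)),
    data.frame(t = rec$perfusions$time_s, pr = 0,
               sym = paste0("Ch", rec$perfusions$to_channel)))
  seq_sym <- paste(ev$sym[order(ev$t, ev$pr)], collapse = " ")
  expected <- paste(
    c("Ch1", rep("P0", 3),                # baseline until uncheck
      "Ch2", rep("P0", 8), "T0",          # inhibitor in, first train
      rep("P0", 3), "Ch1",                # washout begins
      rep("P0", 8), "T0", rep("P0", 8),   # second train, closing sweeps
      "Ch0"),                             # perfusion off at protocol end
    collapse = " ")
  expect_equal(seq_sym, expected)
})

test_that("counted loops run exactly their count", {
  rig <- fixture_rig("slice")
  s <- protocol_script(list(ev_loop(3), ev_sweep("P0sweep"), ev_endloop()))
  rec <- run_protocol(s, rig)
  expect_equal(nrow(rec$sweeps), 3L)
  expect_true(all(rec$sweeps$name == "P0sweep"))
})

test_that("a continuous loop exits at the end of the iteration the uncheck lands in", {
  rig <- fixture_rig("slice")
  s <- fixture_protocol("ltp_circular")
  # time trigger mid-iteration: the current sweep finishes first
  rec <- run_protocol(s, rig, controls = list(
    control_event("uncheck_loop", at_time = 70, loop_index = 1)))
  expect_equal(nrow(rec$sweeps), 3L)  # sweeps start at 0, 30.2, 60.4
})

test_that("RunOnce bodies run once per check", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_runonce"), rig, controls = list(
    control_event("check_runonce", after_sweep = 2, runonce_index = 1),
    control_event("check_runonce", after_sweep = 4, runonce_index = 1),
    control_event("uncheck_loop", after_sweep = 6, loop_index = 1)))
  expect_equal(sum(rec$sweeps$name == "T0sweep"), 2L)
})

test_that("manually evoked sweeps appear in the record as manual", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_circular"), rig, controls = list(
    control_event("single_sweep", after_sweep = 2, sweep_name = "T0sweep"),
    control_event("uncheck_loop", after_sweep = 5, loop_index = 1)))
  expect_equal(sum(rec$sweeps$name == "T0sweep" & rec$sweeps$manual), 1L)
})

test_that("override suppresses scripted perfusion changes", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig, controls = c(
    list(control_event("set_override", at_time = 0, channel = 3)),
    uncheck1(2)))
  p <- rec$perfusions
  expect_true(all(p$suppressed[p$time_s > 0 | p$to_channel %in% 1:2]))
  expect_equal(rec$line_channels[["Slow0"]], 3L)
  expect_match(emit_log(rec), "suppressed")
})

test_that("manual Apply is rejected while running without override", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig, controls = c(
    list(control_event("manual_apply", after_sweep = 1, channel = 5)),
    uncheck1(3)))
  expect_match(rec$warnings, "rejected", all = FALSE)
  expect_false(5L %in% rec$perfusions$to_channel)
})

test_that("set-channel-to-last-perfuse keeps the final solution flowing", {
  rig <- fixture_rig("slice")
  s <- protocol_script(list(ev_perfuse("Slow0", 2), ev_sweep("P0sweep")))
  rec_off <- run_protocol(s, rig)
  expect_equal(rec_off$line_channels[["Slow0"]], 0L)
  expect_equal(rec_off$perfusions$to_channel, c(2L, 0L))
  rec_keep <- run_protocol(s, rig, controls = list(
    control_event("set_ch_to_last_perfuse", value = TRUE)))
  expect_equal(rec_keep$line_channels[["Slow0"]], 2L)
  expect_equal(rec_keep$perfusions$to_channel, 2L)
})

test_that("slow-line perfusion never falls inside a sweep; fast epochs always do", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                      controls = uncheck1(3))
  slow <- rec$perfusions[!rec$perfusions$suppressed, ]
  for (i in seq_len(nrow(slow))) {
    # strictly inside a sweep window (a timestamp shared with a sweep start
    # means the change completed before stimulation began)
    inside <- rec$sweeps$start_time_s < slow$time_s[i] &
      slow$time_s[i] < rec$sweeps$start_time_s + rec$sweeps$duration_s
    expect_false(any(inside))
  }
  rec2 <- run_linked_files(fixture_protocol_path("linked_antag1"),
                           fixture_rig("patch16"))
  ep <- rec2$activations[rec2$activations$source == "epoch", ]
  for (i in seq_len(nrow(ep))) {
    inside <- rec2$sweeps$start_time_s <= ep$time_s[i] + 1e-9 &
      ep$time_s[i] < rec2$sweeps$start_time_s + rec2$sweeps$duration_s
    expect_true(any(inside))
  }
})

test_that("the simulated clock conserves sweep, interval and delay time", {
  rig <- fixture_rig("patch16")
  rec <- run_linked_files(fixture_protocol_path("linked_antag1"), rig)
  expected <- sum(rec$sweeps$duration_s) +
    nrow(rec$sweeps) * rig$inter_sweep_interval_s +
    3 * 30   # one Delay 30 per linked protocol
  expect_equal(rec$end_time_s, expected)
})

test_that("identical inputs and seed reproduce the record exactly", {
  rig <- fixture_rig("slice")
  rig$slow_port_jitter_ms <- 20
  r1 <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                     controls = uncheck1(3), seed = 5)
  r2 <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                     controls = uncheck1(3), seed = 5)
  expect_identical(r1$valve_timeline, r2$valve_timeline)
  expect_identical(r1$log, r2$log)
  # jitter displaces slow actions by at most the configured bound
  lag <- r1$perfusions$switch_time_s - r1$perfusions$time_s
  expect_true(all(lag >= 0 & lag <= 0.020 + 1e-9))
})

test_that("three linked protocols activate 15 distinct solutions", {
  rig <- fixture_rig("patch16")
  rec <- run_linked_files(fixture_protocol_path("linked_antag1"), rig)
  expect_equal(rec$protocols_run,
               c("linked_antag1.proto", "linked_antag2.proto",
                 "linked_antag3.proto"))
  chans <- unique(rec$activations$channel[rec$activations$line == "Fast0"])
  expect_length(chans, 15L)
  expect_setequal(chans, c(1:3, 4:15))
  log <- emit_log(rec)
  expect_match(log, "Loaded protocol 'linked_antag2.proto'", fixed = TRUE)
  expect_match(log, "Started protocol 'linked_antag2.proto'", fixed = TRUE)
})

test_that("a protocol without autostart and without a start control ends the run", {
  rig <- fixture_rig("patch16")
  scripts <- lapply(paste0("linked_antag", 1:2), fixture_protocol)
  rec <- run_linked(scripts, rig, autostart = c(TRUE, FALSE))
  expect_equal(rec$protocols_run, "linked_antag1.proto")
  expect_match(rec$warnings, "no autostart", all = FALSE)
  # with a start control the chain continues
  rec2 <- run_linked(scripts, rig, autostart = c(TRUE, FALSE), controls = list(
    control_event("start_protocol", at_time = 500, protocol = 2)))
  expect_equal(length(rec2$protocols_run), 2L)
  expect_gte(rec2$sweeps$start_time_s[rec2$sweeps$protocol == 2][1], 500)
})

test_that("a missing linked file stops the run with a logged error", {
  dir <- withr::local_tempdir()
  s <- protocol_script(list(ev_sweep("P0sweep")),
                       link = list(next_protocol = "nowhere.proto",
                                   autostart = TRUE))
  write_protocol(s, file.path(dir, "first.proto"))
  rec <- run_linked_files(file.path(dir, "first.proto"), fixture_rig("slice"))
  expect_match(emit_log(rec), "ERROR: linked protocol")
  expect_equal(nrow(rec$sweeps), 1L)
})

test_that("every perfusion, sweep and link event yields exactly one log line", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                      controls = uncheck1(3))
  expect_length(rec$log,
                nrow(rec$perfusions) + nrow(rec$sweeps) + rec$n_link_events)
  rec2 <- run_linked_files(fixture_protocol_path("linked_antag1"),
                           fixture_rig("patch16"))
  expect_length(rec2$log,
                nrow(rec2$perfusions) + nrow(rec2$sweeps) + rec2$n_link_events)
  # log lines carry channel and label
  expect_match(emit_log(rec), "Perfuse Slow0 Ch2 CaMKII Inhibitor",
               fixed = TRUE)
})

test_that("controls aimed at never-reached loops are reported", {
  rig <- fixture_rig("slice")
  s <- protocol_script(list(ev_sweep("P0sweep"), ev_loop(2),
                            ev_sweep("P0sweep"), ev_endloop()))
  rec <- run_protocol(s, rig, controls = list(
    control_event("uncheck_loop", at_time = 1e6, loop_index = 5)))
  expect_length(rec$warnings, 0L)  # loop 5 does not exist in this script
  s2 <- protocol_script(list(ev_loop(99999, TRUE), ev_sweep("P0sweep"),
                             ev_endloop(), ev_loop(99999, TRUE),
                             ev_sweep("T0sweep"), ev_endloop()))
  # loop 2 unreachable in practice: loop 1 exits only at its uncheck, after
  # which we uncheck loop 2 immediately so the run terminates
  rec2 <- run_protocol(s2, rig, controls = list(
    control_event("uncheck_loop", after_sweep = 2, loop_index = 1),
    control_event("uncheck_loop", after_sweep = 3, loop_index = 2)))
  expect_equal(sum(rec2$sweeps$name == "T0sweep"), 1L)
})

test_that("the recirculation line mirrors the perfusion line per policy", {
  rig <- fixture_rig("slice")
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                      controls = uncheck1(3))
  tl <- run_recirculation_policy(rec, c("2" = "recirculate"))
  expect_equal(tl$value, as.numeric(tl$channel == 2L))
  # recirculation engaged exactly while Ch2 flows
  expect_true(all(tl$action[tl$channel == 2L] == "recirculate"))
  # empty policy: constant waste
  expect_true(all(run_recirculation_policy(rec)$value == 0))
  # inverting the policy inverts the trace (over the channels used)
  inv <- run_recirculation_policy(rec, c("1" = "recirculate", "0" = "recirculate"))
  expect_equal(inv$value[tl$channel %in% c(0L, 1L, 2L)],
               1 - tl$value[tl$channel %in% c(0L, 1L, 2L)])
})

test_that("experiment output files are written and consistent", {
  rig <- noiseless_slice_rig()
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig,
                      controls = uncheck1(3))
  sim <- simulate_slice_experiment(rec, rig)
  dir <- withr::local_tempdir()
  write_experiment_dir(rec, dir, rig = rig, sim = sim)
  expect_true(all(file.exists(file.path(dir, c(
    "experiment.log", "timeline.csv", "sweeps.csv", "continuous.csv",
    "spreadsheet.csv")))))
  sheet <- utils::read.csv(file.path(dir, "spreadsheet.csv"))
  expect_equal(nrow(sheet), nrow(rec$sweeps))
  cont <- utils::read.csv(file.path(dir, "continuous.csv"))
  expect_setequal(unique(cont$channel), c(0L, 1L, 2L))
})
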