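# Controller encodings, switch planning, stepper, and design arithmetic.

test_that("analog encoding is channel times per-channel volts", {
  cfg8 <- controller_config(mode = "analog", n_channels = 8,
                            volts_per_channel = 1)
  cfg16 <- controller_config(mode = "analog", n_channels = 16,
                             volts_per_channel = 0.5)
  expect_equal(encode_analog(8, cfg8), 8.0)
  expect_equal(encode_analog(0, cfg8), 0.0)
  expect_equal(encode_analog(15, cfg16), 7.5)
  expect_error(encode_analog(9, cfg8), "out of range")
  expect_error(encode_analog(-1, cfg8), "out of range")
})

test_that("4-bit binary encoding honors each off-code convention", {
  expect_equal(format_bits(encode_binary4(0, "off_code_zero_15ch")), "0000")
  expect_equal(format_bits(encode_binary4(15, "off_code_zero_15ch")), "1111")
  expect_equal(format_bits(encode_binary4(5, "8ch")), "0101")
  expect_equal(format_bits(encode_binary4(1, "full_16ch")), "0000")
  expect_equal(format_bits(encode_binary4(16, "full_16ch")), "1111")
  expect_error(encode_binary4(16, "off_code_zero_15ch"), "out of range")
  expect_error(encode_binary4(0, "full_16ch"), "out of range")
})

test_that("4-bit binary encoding is injective within each convention", {
  for (conv in c("8ch", "off_code_zero_15ch", "full_16ch")) {
    rng <- switch(conv, "8ch" = 0:8, "off_code_zero_15ch" = 0:15,
                  "full_16ch" = 1:16)
    codes <- vapply(rng, function(ch) format_bits(encode_binary4(ch, conv)), "")
    expect_equal(anyDuplicated(codes), 0L)
  }
})

test_that("valve-bit encoding maps channel n to bit n-1", {
  cfg <- controller_config(mode = "valvebits", n_channels = 8)
  expect_equal(encode_valvebits(1, cfg), 1L)     # bit0 only
  expect_equal(encode_valvebits(2, cfg), 2L)     # bit1 only
  expect_equal(encode_valvebits(0, cfg), 0L)     # all off
  expect_equal(encode_valvebits(8, cfg), 128L)
})

test_that("a standard switch closes the old valve and opens the new one together", {
  cfg <- controller_config(mode = "valvebits", n_channels = 8, port = "Port1")
  plan <- plan_standard_switch(1, 2, cfg)
  expect_equal(nrow(plan), 2L)
  expect_true(all(plan$time_s == 0))
  expect_equal(plan$bit[plan$value == 0], 0L)  # Ch1 valve -> Bit0 off
  expect_equal(plan$bit[plan$value == 1], 1L)  # Ch2 valve -> Bit1 on
  expect_equal(nrow(plan_standard_switch(3, 3, cfg)), 0L)
  acfg <- controller_config(mode = "analog", n_channels = 8)
  aplan <- plan_standard_switch(1, 2, acfg)
  expect_equal(nrow(aplan), 1L)
  expect_equal(aplan$value, 2.0)
})

test_that("the pre-flush sequence flushes, then swaps chamber valves at once", {
  cfg <- controller_config(mode = "valvebits", n_channels = 4,
                           valves_per_channel = 2, port = "Port1")
  plan <- plan_preflush_switch(1, 2, 10, cfg)
  # flush valve of Ch2 = bit5 on at t=0; at t=10 bit5 off, bit1 on, bit0 off
  expect_equal(plan$time_s, c(0, 10, 10, 10))
  expect_equal(plan$bit, c(5L, 5L, 1L, 0L))
  expect_equal(plan$value, c(1, 0, 1, 0))
  # symmetric direction
  back <- plan_preflush_switch(2, 1, 10, cfg)
  expect_equal(back$bit, c(4L, 4L, 0L, 1L))
  expect_equal(back$value, c(1, 0, 1, 0))
  expect_equal(open_chamber_channels(plan, cfg), 2L)
  expect_error(plan_preflush_switch(1, 2, 0, cfg), "flush_duration")
  expect_error(plan_preflush_switch(1, 2, 10,
    controller_config(mode = "valvebits", n_channels = 8)), "2-valves")
})

test_that("flow-to-waste switching is a single simultaneous toggle", {
  cfg <- controller_config(mode = "valvebits", n_channels = 8)
  plan <- plan_flow_to_waste_switch(1, 2, cfg)
  expect_true(all(plan$time_s == 0))
  expect_equal(sort(plan$bit), c(0L, 1L))
  off <- plan_flow_to_waste_switch(2, 0, cfg)
  expect_equal(open_chamber_channels(off, cfg), integer())  # all to waste
})

test_that("exactly one chamber path is open after any switch plan", {
  set.seed(3)
  cfgs <- list(
    controller_config(mode = "valvebits", n_channels = 8),
    controller_config(mode = "analog", n_channels = 16,
                      volts_per_channel = 0.5),
    controller_config(mode = "valvebits", n_channels = 4,
                      valves_per_channel = 2))
  for (cfg in cfgs) {
    for (k in 1:20) {
      from <- sample(0:cfg$n_channels, 1)
      to <- sample(1:cfg$n_channels, 1)
      plan <- if (cfg$valves_per_channel == 2L)
        plan_preflush_switch(from, to, 10, cfg)
      else plan_standard_switch(from, to, cfg)
      expect_equal(open_chamber_channels(plan, cfg), to)
    }
  }
})

test_that("pre-flush and standard plans end in identical chamber-valve state", {
  cfg1 <- controller_config(mode = "valvebits", n_channels = 4)
  cfg2 <- controller_config(mode = "valvebits", n_channels = 4,
                            valves_per_channel = 2)
  for (pair in list(c(1, 2), c(2, 4), c(3, 1))) {
    std <- plan_standard_switch(pair[1], pair[2], cfg1)
    pf <- plan_preflush_switch(pair[1], pair[2], 10, cfg2)
    expect_equal(open_chamber_channels(std, cfg1),
                 open_chamber_channels(pf, cfg2))
    # extra pre-flush actions all precede or coincide with switch-over and
    # touch only flush bits
    flush_acts <- pf[pf$bit >= 4L, ]
    expect_gte(nrow(flush_acts), 1L)
  }
})

test_that("the stepper positions tubes at 1 V per tube index", {
  cfg <- stepper_config()
  expect_equal(stepper_move(0, cfg)$value, 0.0)
  expect_equal(stepper_move(1, cfg)$value, 1.0)
  expect_equal(stepper_move(2, cfg)$value, 2.0)
  dual <- stepper_config(tubes = 0:1)
  expect_error(stepper_move(2, dual), "not configured")
})

test_that("dead volume matches the printed tubing estimates", {
  expect_equal(round(dead_volume(tubing_segment(9, 0.8)), 2), 0.05)
  expect_equal(round(dead_volume(tubing_segment(16, 0.8)), 2), 0.08)
  expect_equal(dead_volume(tubing_segment(0, 0.8)), 0)
})

test_that("solution counts follow the binding arithmetic", {
  expect_equal(solutions_required(4, 4, TRUE), 8L)
  expect_equal(solutions_required(4, 3, FALSE), 15L)
  expect_equal(solutions_required(0, 1, TRUE), 1L)
  expect_equal(solutions_required(0, 1, FALSE), 1L)
  expect_equal(max_solutions(3, 16), 48L)
  expect_equal(max_solutions(2, 16), 32L)
  expect_equal(max_solutions(1, 8), 8L)
})

test_that("controller invariants are enforced at construction", {
  expect_error(controller_config(mode = "valvebits", n_channels = 8,
                                 valves_per_channel = 2, port = "Port1"),
               "at most 4 channels")
  # 16-bit dual port does allow 8 pre-flush channels
  expect_s3_class(controller_config(mode = "valvebits", n_channels = 8,
                                    valves_per_channel = 2, port = "Port1+2"),
                  "controller_config")
})
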