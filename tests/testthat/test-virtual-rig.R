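# Plug-flow transport and trace synthesis.

std_model <- function(rj = 40, jm = 9, mc = 5, flow = 2, chamber = 1) {
  transport_model(list(
    tubing_segment(rj, 0.8, "reservoir_to_junction"),
    tubing_segment(jm, 0.8, "junction_to_manifold"),
    tubing_segment(mc, 0.8, "manifold_to_chamber")), flow, chamber)
}

test_that("a standard switch delivers a stale bolus of duration Vs/Q", {
  tm <- std_model()
  q <- tm$flow_rate_ml_min / 60
  sw <- data.frame(time_s = c(0, 100), to_channel = c(1, 2),
                   scheme = "standard", solute = c("A", "B"))
  out <- advance_transport(tm, sw, dt = 0.05, t_end = 300)
  # after the manifold-to-chamber content clears, stale solution flows for
  # Vs/Q seconds
  t_arrive <- 100 + tm$v_manifold_chamber / q
  dur <- stale_bolus_volume(tm, "standard") / q
  stale <- out$time_s[out$time_s > 50 & out$inflow_stale > 0.5]
  expect_equal(min(stale), t_arrive, tolerance = 0.02)
  expect_equal(max(stale) - min(stale), dur, tolerance = 0.02)
})

test_that("pre-flush delivers strictly less stale volume than standard", {
  set.seed(21)
  for (k in 1:10) {
    tm <- std_model(rj = runif(1, 5, 80), jm = runif(1, 2, 20),
                    mc = runif(1, 1, 10))
    expect_lt(stale_bolus_volume(tm, "preflush"),
              stale_bolus_volume(tm, "standard"))
    expect_equal(stale_bolus_volume(tm, "flow_to_waste"),
                 stale_bolus_volume(tm, "preflush"))
    # and the integrated stale inflow reflects it
    sw <- data.frame(time_s = 50, to_channel = 2, scheme = "standard",
                     solute = "B")
    swp <- transform(sw, scheme = "preflush")
    o1 <- advance_transport(tm, sw, dt = 0.1, t_end = 150,
                            initial_solute = "A")
    o2 <- advance_transport(tm, swp, dt = 0.1, t_end = 150,
                            initial_solute = "A")
    q <- tm$flow_rate_ml_min / 60
    expect_equal(sum(o1$inflow_stale) * 0.1 * q,
                 stale_bolus_volume(tm, "standard"), tolerance = 0.02)
    expect_lt(sum(o2$inflow_stale), sum(o1$inflow_stale))
  }
})

test_that("with zero dead volume the new solution arrives at switch time", {
  tm <- transport_model(list(tubing_segment(0, 0.8, "junction_to_manifold")),
                        2, 1)
  sw <- data.frame(time_s = c(0, 60), to_channel = c(1, 2),
                   scheme = "preflush", solute = c("A", "B"))
  out <- advance_transport(tm, sw, dt = 0.1, t_end = 120)
  first_b <- min(out$time_s[out$inflow_B > 0.5])
  expect_equal(first_b, 60, tolerance = 0.11)
})

test_that("transport conserves composition: inflow and chamber fractions sum to one", {
  tm <- std_model()
  sw <- data.frame(time_s = c(0, 30, 90), to_channel = c(1, 2, 1),
                   scheme = "standard", solute = c("A", "B", "A"))
  out <- advance_transport(tm, sw, dt = 0.2, t_end = 200)
  expect_equal(out$inflow_A + out$inflow_B, rep(1, nrow(out)))
  expect_equal(out$chamber_A + out$chamber_B, rep(1, nrow(out)),
               tolerance = 1e-9)
  expect_true(all(out$chamber_stale >= 0 & out$chamber_stale <= 1))
})

test_that("noiseless field sweeps measure exactly the pathway slope", {
  slice <- slice_model(noise_sd = 0)
  p0 <- fixture_rig("slice")$sweep_defs$P0sweep
  tr <- synth_field_sweep(slice, p0)
  win <- p0$s0_train$onset_ms + slice$slope_window_ms
  expect_equal(measure_slope(tr, win), slice$baseline_slope)
  tr2 <- synth_field_sweep(slice, p0, slope = -0.4)
  expect_equal(measure_slope(tr2, win), -0.4)
  nostim <- sweep_def("P0sweep", duration_ms = 50)
  expect_error(synth_field_sweep(slice, nostim), "no S0")
})

test_that("the induction rule follows chamber inhibitor concentration", {
  rig <- noiseless_slice_rig()
  rec <- run_protocol(fixture_protocol("ltp_perfusion"), rig, controls = list(
    control_event("uncheck_loop", after_sweep = 3, loop_index = 1)))
  sim <- simulate_slice_experiment(rec, rig)
  expect_equal(nrow(sim$trains), 2L)
  expect_gte(sim$trains$inhibitor_conc[1], rig$slice$block_threshold)
  expect_false(sim$trains$potentiated[1])   # train in inhibitor: blocked
  expect_lt(sim$trains$inhibitor_conc[2], rig$slice$block_threshold)
  expect_true(sim$trains$potentiated[2])    # train in washout: potentiates
  expect_equal(sim$final_slope,
               rig$slice$baseline_slope * rig$slice$ltp_factor)
})

test_that("patch responses follow the Hill curve with a Schild shift", {
  pm <- patch_model(noise_sd = 0)
  n <- 4000
  dt <- 1
  zero <- synth_patch_sweep(pm, rep(0, n), 0, dt_ms = dt)
  expect_true(all(zero$samples == 0))
  sat <- synth_patch_sweep(pm, rep(1000 * pm$EC50, n), 0, dt_ms = dt)
  expect_equal(sat$samples[n], pm$Emax, tolerance = 1e-3)
  # B = Ki doubles the apparent EC50: at c = EC50 the steady state falls to
  # Emax / (1 + 2^h)
  half <- synth_patch_sweep(pm, rep(pm$EC50, n), pm$Ki, dt_ms = dt)
  expect_equal(half$samples[n], pm$Emax / (1 + 2^pm$hill_h),
               tolerance = 1e-3)
  # noisy synthesis is seed-reproducible
  pmn <- patch_model(noise_sd = 5, rng_seed = 7)
  a <- synth_patch_sweep(pmn, rep(pm$EC50, 100))
  b <- synth_patch_sweep(pmn, rep(pm$EC50, 100))
  expect_identical(a$samples, b$samples)
  c2 <- synth_patch_sweep(pmn, rep(pm$EC50, 100), seed = 8)
  expect_false(identical(a$samples, c2$samples))
})

test_that("seal-test transients match their closed forms", {
  pm <- patch_model(Rs_MOhm = 10, Rin_MOhm = 150, Cm_pF = 30, noise_sd = 0)
  tr <- synth_seal_test(pm, 10)
  expect_equal(tr$samples[1], 1000 * 10 / 10)           # peak = step/Rs
  expect_equal(tr$samples[length(tr$samples)],
               1000 * 10 / 160, tolerance = 1e-4)       # steady = step/(Rs+Rin)
  tau <- 10 * 30 / 1000
  i_at_tau <- 1000 * 10 / 160 + (1000 - 1000 * 10 / 160) * exp(-1)
  k <- which.min(abs(trace_times <- (seq_along(tr$samples) - 1) * tr$dt_ms - tau))
  expect_equal(tr$samples[k], i_at_tau, tolerance = 0.5)
  expect_error(synth_seal_test(patch_model(Rs_MOhm = 0), 10), "unbounded")
})
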