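# Measurement battery: slopes, waveform geometry, resistances.

test_that("OLS slope recovers exact and noisy linear trends", {
  t <- (0:99) * 0.1
  lin <- trace(2 * t, dt_ms = 0.1)
  expect_equal(measure_slope(lin, c(0, 9.9)), 2.0)
  expect_equal(measure_slope(trace(rep(3, 50), dt_ms = 0.1), c(0, 4.9)), 0.0)
  # noisy line: estimate within 3 standard errors of the true slope
  set.seed(9)
  sd_noise <- 0.1
  for (k in 1:5) {
    y <- 1.7 * t + rnorm(100, 0, sd_noise)
    est <- measure_slope(trace(y, dt_ms = 0.1), c(0, 9.9))
    se <- sd_noise / sqrt(sum((t - mean(t))^2))
    expect_lt(abs(est - 1.7), 3 * se)
  }
  expect_error(measure_slope(lin, c(20, 30)), "outside")
})

test_that("max slope finds the steepest subwindow", {
  t <- (0:299) * 0.1
  lin <- trace(2 * t, dt_ms = 0.1)
  expect_equal(measure_max_slope(lin, c(0, 29.9), 2), 2.0)
  # piecewise line with a steep middle segment
  y <- c(0.5 * t[1:100],
         0.5 * t[100] + 5 * (t[101:200] - t[100]),
         0.5 * t[100] + 5 * (t[200] - t[100]) + 0.2 * (t[201:300] - t[200]))
  pw <- trace(y, dt_ms = 0.1)
  # brute-force oracle over all subwindows
  m <- 21L
  brute <- max(vapply(1:(300 - m + 1), function(i) {
    idx <- i:(i + m - 1)
    stats::cov(t[idx], y[idx]) / stats::var(t[idx])
  }, 0))
  expect_equal(measure_max_slope(pw, c(0, 29.9), 2), brute)
  expect_equal(brute, 5, tolerance = 1e-6)
  # sigmoid: attained near the inflection, equal to the numeric maximum
  s <- 1 / (1 + exp(-(t - 15)))
  sg <- trace(s, dt_ms = 0.1)
  ms <- measure_max_slope(sg, c(0, 29.9), 1)
  # max derivative of the logistic is 0.25; a 1 ms window averages it down a little
  expect_equal(ms, 0.25, tolerance = 0.05)
  expect_error(measure_max_slope(lin, c(0, 29.9), 0.1), "fewer than 3")
})

test_that("max slope dominates the window slope for arbitrary traces", {
  set.seed(13)
  for (k in 1:10) {
    y <- cumsum(rnorm(200))
    tr <- trace(y, dt_ms = 0.1)
    expect_gte(measure_max_slope(tr, c(0, 19.9), 5) + 1e-12,
               measure_slope(tr, c(0, 19.9)))
  }
})

test_that("square-pulse geometry: peak 1, area w, duration w", {
  w_ms <- 20
  y <- c(rep(0, 100), rep(1, 200), rep(0, 100))
  tr <- trace(y, dt_ms = 0.1)
  expect_equal(measure_basic(tr, "peak_amplitude", c(0, 39.9)), 1)
  expect_equal(measure_basic(tr, "area", c(0, 39.9)), w_ms, tolerance = 0.01)
  expect_equal(measure_basic(tr, "duration", c(0, 39.9)), w_ms,
               tolerance = 0.01)
  expect_equal(measure_basic(tr, "average_amplitude", c(10.5, 29.5)), 1)
})

test_that("peak-relative kinds fail cleanly on a flat trace", {
  flat <- trace(rep(2, 100), dt_ms = 0.1)
  expect_equal(measure_basic(flat, "peak_amplitude", c(0, 9.9),
                             baseline_window = c(0, 1)), 0)
  expect_error(measure_basic(flat, "rise_time", c(0, 9.9),
                             baseline_window = c(0, 1)), "flat trace")
  expect_error(measure_basic(flat, "decay_time", c(0, 9.9),
                             baseline_window = c(0, 1)), "flat trace")
})

test_that("rise, decay and pop-spike follow their standard definitions", {
  t <- seq(0, 40, by = 0.05)
  # smooth biexponential deflection
  y <- (exp(-(t - 5) / 8) - exp(-(t - 5) / 1.5))
  y[t < 5] <- 0
  tr <- trace(-y, dt_ms = 0.05)   # negative-going
  rise <- measure_basic(tr, "rise_time", c(0, 40))
  dec <- measure_basic(tr, "decay_time", c(0, 40))
  expect_gt(rise, 0); expect_gt(dec, rise)
  # decay to 37% of a pure exponential tail is about one time constant
  ypk <- max(y)
  t_pk <- t[which.max(y)]
  t_37 <- t[t > t_pk][which.min(abs(y[t > t_pk] - 0.37 * ypk))]
  expect_equal(dec, t_37 - t_pk, tolerance = 0.1)

  # synthetic population spike: trough at depth a below the chord between
  # two positive humps
  a <- 3
  ps <- 2 * exp(-((t - 12) / 2.5)^2) + 2 * exp(-((t - 28) / 2.5)^2) -
    a * exp(-((t - 20) / 1.5)^2) + 2 * dnorm(0)  # constant baseline offset
  pst <- trace(ps, dt_ms = 0.05)
  got <- measure_basic(pst, "pop_spike", c(5, 35))
  # direct chord oracle
  itr <- which.min(ps); i1 <- which.max(ps[t < 20]); i2 <- which.max(ps)
  left <- which.max(ps[1:itr]); right <- itr - 1 + which.max(ps[itr:length(ps)])
  chord <- ps[left] + (ps[right] - ps[left]) * (t[itr] - t[left]) /
    (t[right] - t[left])
  expect_equal(got, chord - ps[itr])
})

test_that("linearity and time-shift invariance hold across measurements", {
  set.seed(17)
  t <- seq(0, 40, by = 0.05)
  y <- (exp(-(t - 5) / 8) - exp(-(t - 5) / 1.5)) + rnorm(length(t), 0, 0.002)
  y[t < 5] <- rnorm(sum(t < 5), 0, 0.002)
  tr <- trace(y, dt_ms = 0.05)
  trk <- trace(3 * y, dt_ms = 0.05)
  shifted <- trace(y, dt_ms = 0.05, t0_ms = 100)
  win <- c(0, 40); base <- c(0, 4)
  for (kind in c("peak_amplitude", "average_amplitude", "area")) {
    v <- measure_basic(tr, kind, win, base)
    expect_equal(measure_basic(trk, kind, win, base), 3 * v)
    expect_equal(measure_basic(shifted, kind, win + 100, base + 100), v)
  }
  for (kind in c("rise_time", "decay_time", "duration")) {
    v <- measure_basic(tr, kind, win, base)
    expect_equal(measure_basic(trk, kind, win, base), v)
    expect_equal(measure_basic(shifted, kind, win + 100, base + 100), v)
  }
  expect_equal(measure_slope(trk, c(5.5, 7)), 3 * measure_slope(tr, c(5.5, 7)))
})

test_that("input resistance is the steady-state deflection over the step", {
  # current clamp: 100 pA step deflecting a mV trace by 10 mV
  v <- c(rep(0, 100), rep(10, 200))
  tr <- trace(v, dt_ms = 0.1)
  expect_equal(input_resistance(tr, step_pA = 100, window = c(20, 29),
                                baseline_window = c(0, 9)), 100)
  expect_equal(input_resistance(trace(rep(0, 100), dt_ms = 0.1),
                                step_pA = 100, window = c(5, 9)), 0)
  expect_error(input_resistance(tr, step_pA = 0, window = c(20, 29)), "zero")
  # voltage clamp on the virtual seal test: recover Rin within 2%
  pm <- patch_model(noise_sd = 0)
  st <- synth_seal_test(pm, 10)
  rin <- input_resistance(st, step_mV = 10, window = c(4, 4.9)) - pm$Rs_MOhm
  expect_equal(rin, pm$Rin_MOhm, tolerance = 0.02)
})

test_that("series resistance is recovered from noiseless transients", {
  pm <- patch_model(Rs_MOhm = 10, noise_sd = 0)
  fit <- series_resistance_fit(synth_seal_test(pm, 10), 10, n_exp = 1)
  expect_equal(fit$Rs_MOhm, 10, tolerance = 0.01)
  expect_equal(fit$tau_ms, pm$Rs_MOhm * pm$Cm_pF / 1000, tolerance = 0.01)

  pm2 <- patch_model(Rs_MOhm = 10, noise_sd = 0,
                     rs_second = list(frac = 0.3, tau_ms = 1.2))
  fit2 <- series_resistance_fit(synth_seal_test(pm2, 10, duration_ms = 12),
                                10, n_exp = 2)
  expect_equal(fit2$Rs_MOhm, 10, tolerance = 0.02)
  expect_equal(fit2$tau_ms, sort(c(0.3, 1.2)), tolerance = 0.05)

  expect_error(series_resistance_fit(trace(rep(5, 100), dt_ms = 0.02), 10),
               "flat transient")
})

test_that("series-resistance recovery stays within 5% under 2% peak noise", {
  true_rs <- 10
  errs <- vapply(1:100, function(k) {
    pm <- patch_model(Rs_MOhm = true_rs, noise_sd = 0.02 * 1000 * 10 / true_rs,
                      rng_seed = 1000 + k)
    fit <- series_resistance_fit(synth_seal_test(pm, 10), 10)
    abs(fit$Rs_MOhm - true_rs) / true_rs
  }, 0)
  expect_lt(stats::median(errs), 0.05)
})
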