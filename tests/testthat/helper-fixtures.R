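# Shared helpers: deterministic rigs and random-script generation.

noiseless_slice_rig <- function() {
  rig <- fixture_rig("slice")
  rig$slice <- slice_model(noise_sd = 0)
  rig
}

# random but valid protocol script: flat or nested loops over sweeps,
# delays and perfusion changes
random_script <- function(n_events = 8, n_channels = 8) {
  ev <- list()
  depth <- 0L
  for (k in seq_len(n_events)) {
    pick <- sample(c("loop", "sweep", "delay", "perfuse", "end"), 1,
                   prob = c(0.2, 0.35, 0.15, 0.2, 0.1))
    if (pick == "loop" && depth < 2L) {
      ev <- c(ev, list(ev_loop(sample(c(1:5, 99999), 1),
                               continuous = stats::runif(1) < 0.2)))
      depth <- depth + 1L
    } else if (pick == "end" && depth > 0L) {
      ev <- c(ev, list(ev_endloop()))
      depth <- depth - 1L
    } else if (pick == "delay") {
      ev <- c(ev, list(ev_delay(round(stats::runif(1, 0, 60), 1))))
    } else if (pick == "perfuse") {
      ev <- c(ev, list(ev_perfuse(sample(PERFUSION_LINES, 1),
                                  sample.int(n_channels, 1))))
    } else {
      ev <- c(ev, list(ev_sweep(sample(c("P0sweep", "T0sweep"), 1))))
    }
  }
  while (depth > 0L) {
    ev <- c(ev, list(ev_endloop()))
    depth <- depth - 1L
  }
  labs <- data.frame(line = "Slow0", channel = 1:2,
                     label = c("ACSF", "Drug X"))
  protocol_script(ev, labels = labs, name = "random")
}

# structural equality of two scripts, ignoring names/attributes noise
expect_script_equal <- function(a, b) {
  expect_equal(length(a$events), length(b$events))
  for (i in seq_along(a$events))
    expect_equal(unclass(a$events[[i]]), unclass(b$events[[i]]))
  expect_equal(a$labels[order(a$labels$line, a$labels$channel), ],
               b$labels[order(b$labels$line, b$labels$channel), ],
               ignore_attr = TRUE)
  expect_equal(a$link, b$link)
  expect_length(b$sweep_overrides, length(a$sweep_overrides))
  if (length(a$sweep_overrides))
    expect_equal(a$sweep_overrides[order(names(a$sweep_overrides))],
                 b$sweep_overrides[order(names(b$sweep_overrides))])
}
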