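Package: perfusim
Title: Simulation of Automated Stimulation and Perfusion Control in
    Electrophysiology Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hardware-free simulator of automated slice and patch-clamp
    electrophysiology experiments. Provides a line-oriented protocol
    scripting language (loops, delays, stimulation sweeps, perfusion
    changes), valve-controller output encodings and switch sequencing
    (standard, pre-flush, continuous-flow-to-waste, and stepper-driven
    fast perfusion), a discrete-event protocol interpreter with simulated
    operator actions and protocol linking, a virtual rig that models
    plug-flow solution transport and synthesizes field EPSP, agonist
    concentration-response and seal-test traces, and the standard online
    measurement battery (slope, maximum slope, peak, area, rise and decay
    times, population-spike amplitude, input and series resistance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
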