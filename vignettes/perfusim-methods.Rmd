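---
title: "Simulating automated stimulation and perfusion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated stimulation and perfusion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

`perfusim` simulates the control engine of automated electrophysiology
experiments: the protocol script that sequences stimulation sweeps and
perfusion changes, the valve controllers that realize those changes, the
hydraulics that determine which solution actually bathes the preparation,
and the per-sweep measurements. This vignette explains the models, their
assumptions, the parameters that matter, and the design decisions taken
where conventions differ between real systems.

## The protocol language and its execution semantics

A protocol is an ordered list of events between `MainProtocol` and
`EndProtocol`. Three semantic choices deserve explanation:

* **Continuous loops.** Acquisition GUIs encode "loop until I say stop" as
  a checkbox alongside a loop count of 99 999. We store both: the count is
  kept for fidelity on serialization, but execution is governed by the
  `continuous` flag, and a continuous loop exits only when its
  `uncheck_loop` control event fires. The exit test runs at the *end* of
  each iteration, so an uncheck arriving mid-sweep lets the current sweep
  finish — this matches how an operator unchecking a checkbox mid-sweep
  would experience the GUI.
* **Between-sweep vs within-sweep changes.** `Perfuse` events on the slow
  lines (`Slow0`, `Slow1`) execute between sweeps only; fast within-sweep
  changes are expressed as sweep epochs (below), never as slow-line events.
  Slow-port actions optionally carry a latency jitter (default 0, bounded
  at 50 ms) reflecting static digital ports that are accurate to
  milliseconds rather than microseconds; fast-port events are exact.
* **`Run`/`ElseRun`.** These event names exist in real protocol builders
  but their branch semantics are not specified anywhere we could anchor
  them, so the parser accepts them and validation flags them as
  unsupported, rather than guessing.

When a protocol finishes, all lines are switched off unless a
`set_ch_to_last_perfuse` control asked to keep the final solution flowing —
the conservative default for a rig left unattended.

## Sweeps, epochs and the −1 sentinel

A sweep definition carries its pulse trains (onset, count, interval,
width), command steps, and exactly three IC1 epochs. Epoch amplitudes are
in *channel units*: amplitude 8 selects channel 8, and the controller's
volts/channel (1 V for 8-channel, 0.5 V for 16-channel hardware) converts
to the output voltage at render time. This resolves an ambiguity in vendor
conventions — some display the epoch field in volts assuming 1 V/channel
even on 0.5 V/channel hardware. Both behaviors are supported; the
`amplitude_units = "volts"` controller flag switches to literal volts. The
amplitude −1 is a sentinel meaning "hold whatever channel the fast line's
last `Perfuse` event selected", which is what lets one sweep definition
serve every ongoing-antagonist condition.

Waveforms default to 10 kHz sampling. Pulse edges are scheduled at exact
times (`onset + k·interval`) and then quantized per edge, so a 100-pulse
train accumulates no rounding drift; tests assert edge times, not sample
indices. Each protocol file may override the epoch amplitudes of a sweep
(`[sweeps]` block), because linked protocol files routinely reuse the same
four sweep shapes with different perfusion channels.

## Valve switching schemes

Three plumbing schemes are modeled, distinguished by which volume of stale
(unoxygenated, pH-shifted) solution they deliver on a switch:

* **Standard** (1 valve/line): old valve closes and new valve opens
  simultaneously; the whole reservoir-to-manifold volume of the incoming
  line arrives stale.
* **Pre-flush** (2 valves/line): the incoming line's flush valve opens for
  `flush_duration_s`, clearing reservoir-to-junction; at switch-over the
  flush valve closes, the incoming chamber valve opens and the outgoing one
  closes, all simultaneously. Only the junction-to-manifold volume arrives
  stale. The bit layout puts chamber valves on bits 0…n−1 and flush valves
  on bits n…2n−1, anchored by the convention that channel 2's flush valve
  sits on bit 5 in a 4-channel system. The default flush duration is 10 s —
  real systems flush "for a sufficient time" without a canonical number;
  at 2 ml/min a 10 s flush clears 0.33 ml, comfortably above the ~0.2 ml
  reservoir-to-junction volume of the default geometry.
* **Continuous-flow-to-waste** (1 three-way valve/line): unselected lines
  flow to waste permanently, so only junction-to-manifold arrives stale.

Channel 0 means "all off" in every encoding mode (0 V, code 0000, empty
valve word); the 4-bit binary conventions (`8ch`, `off_code_zero_15ch`,
`full_16ch`) are all exposed because 4-bit controllers genuinely differ in
whether they reserve an off code. Plans satisfy a one-open-valve invariant:
after any plan, exactly the target chamber valve is open.

The stepper for dual/triple-line patch rigs is modeled as an analog output
at 1 V per tube index; tube moves during sweeps are ordinary epochs on the
stepper's line (channels 0–2 are tubes 0–2).

## The virtual rig

The transport model is deliberately minimal: **plug flow** (no axial
mixing) through tubing segments of volume π(d/2)²L, a per-switch stale
bolus of the scheme's dead volume, and a **well-mixed chamber** updated
exactly as `C ← C + (x − C)(1 − e^{−QΔt/V})` per step. Staleness is a
scalar fraction, not an O₂/CO₂/pH chemistry model. Defaults — 0.8 mm ID
tubing, 9 cm junction-to-manifold, 2 ml/min, 1 ml chamber, 30 s sweep
pacing — are the geometry and pacing a bench slice rig actually uses; the
junction-to-manifold run alone holds ≈0.05 ml.

The response models are the simplest forms that make every executor and
analysis path exercisable, fully parameterized and with seeded noise:

* **fEPSP**: per stimulus pulse, a compactly supported fiber-volley bump
  followed by a negative difference-of-exponentials (τ rise 1.5 ms, decay
  8 ms). The synaptic component is rescaled so that the OLS slope over the
  model's slope window (default 1–3 ms post-pulse) equals the pathway slope
  *exactly* in the noiseless case — this makes slope tests closed-form
  rather than tolerance-based. The volley is zero outside 0.2–0.9 ms so it
  cannot leak into the slope window.
* **Plasticity rule**: each train sweep multiplies the pathway slope by
  `ltp_factor` (default 1.5) unless the chamber concentration of an
  inhibitor channel's solution is at or above `block_threshold` (default
  0.5) at train onset. This is a rule, not a kinase model: it is the
  minimal biology that makes the perfusion timing observable in the
  measurements.
* **Patch currents**: Hill activation with competitive Schild shift,
  `Emax·c^h/(c^h + (EC50(1+B/Ki))^h)`, relaxing with τ_on/τ_off
  (50/100 ms defaults). **Seal tests** are RC transients: peak ΔV/Rs,
  τ = Rs·Cm (0.3 ms at the 10 MΩ/30 pF defaults), steady state
  ΔV/(Rs+Rin), with an optional second slower exponential emulating
  imperfect compensation.

What passing tests show, therefore, is that the *engine* — sequencing,
encodings, transport timing, measurement definitions — is correct under
idealized responses. They do not show robustness to real-data features the
generator omits: electrode drift, temperature effects, spontaneous events,
receptor desensitization, manifold mixing, or non-stationary noise.

## Measurement definitions and numerics

The measurement battery uses standard definitions, all config-overridable:
OLS slope; maximum slope as the maximum of sliding OLS slopes at 1-sample
stride (computed with rolling sums); peak as the signed extreme deviation
from the baseline-window mean; 10–90 % rise time and full width at half
maximum with linear interpolation at threshold crossings; decay time to
37 % of peak (≈ one time constant; an exponential-fit convention could be
substituted via `decay_fraction`); population spike as the vertical drop
from the trough to the chord joining the flanking positive peaks. Input
resistance is the steady-state deflection over the step (mV/pA → GΩ,
reported in MΩ). Series resistance fits
`I(t) = I_ss + ΣA_i e^{−t/τ_i}` from the transient peak by
Levenberg–Marquardt (`minpack.lm::nlsLM`), seeded from a log-linear fit of
the early decay, with τ bounded in [0.01 ms, 10 × window]; the peak is
back-extrapolated as `I_ss + ΣA_i` and `Rs = ΔV/I_peak`. Degenerate inputs
fail loudly: flat traces for peak-relative kinds, zero steps, transients
below four noise standard deviations.

## Problem sizes

The shipped examples are the full worked experiments, not scaled-down
versions: a 32-sweep LTP run (~16 simulated minutes), three linked
protocols totalling 36 sweeps and 15 solutions, 100-pulse trains at 10 kHz,
and parameter-recovery batteries of 50–100 seeded synthetic traces. The
whole test suite executes in well under a minute on one core because all
time is simulated.

## Known limitations

No hardware I/O or real-time operation; no ramp/train analog command
stimulation; no stimulus-amplitude increment/decrement (so no automated
input–output curves); no automated baseline-stability detection — the
baseline loop ends when the simulated operator unchecks it, as on the real
system; gap-free records are CSV, not vendor binary formats.
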