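# perfusim

Hardware-free simulation of automated stimulation/perfusion experiments in
slice and patch-clamp electrophysiology.

Long-term potentiation (LTP) and concentration–response experiments are, at
bottom, a timed sequence of stimulation sweeps and solution changes. Modern
acquisition programs script that sequence — loops of baseline sweeps,
induction trains, and `Perfuse` events that drive valve controllers — so
that after baseline stability one click runs the whole experiment.
`perfusim` re-creates that engine without any DAQ boards, valves or tissue,
for people who design, teach or test such experiments: protocol authors who
want to dry-run a script and see exactly which valve bits fire when; and
tool developers who need a deterministic, fully observable rig.

The package provides:

* **A protocol-script language** (`.proto` text files): `Loop` (counted, or
  continuous with the 99 999 sentinel), `Delay`, sweep events
  (`P0sweep`/`P1sweep` single-pulse, `T0sweep`/`T1sweep` trains), `Perfuse
  <line> <channel>`, and `RunOnce` blocks, plus solution labels, per-script
  sweep-epoch overrides and protocol linking.
* **Valve-controller encodings and switch sequencing.** Channel *n* becomes
  an analog voltage (*n* × volts/channel), a 4-bit binary code, or a
  one-bit-per-valve word. Switch plans implement standard (close old valve,
  open new valve simultaneously), pre-flush (flush the incoming line to
  waste, then swap chamber valves at once) and continuous-flow-to-waste
  schemes, and a stepper for millisecond tube changes (1 V per tube).
* **A discrete-event executor** with simulated operator actions (unchecking
  the baseline loop, checking a RunOnce, manual/override perfusion),
  experimental-log emission and linked-protocol chains.
* **A virtual rig.** Plug flow moves solution plugs of volume *V* through
  the tubing in time *V/Q*; each switch delivers a stale bolus whose volume
  depends on the switching scheme (π(d/2)²L per tubing segment); the
  chamber is a well-mixed compartment. On top of that sit parameterized
  response models: an fEPSP template whose initial slope is the pathway
  state, Hill/Schild agonist–antagonist currents
  `I = Emax·c^h / (c^h + (EC50·(1 + B/Ki))^h)`, and RC seal-test transients
  (peak ΔV/Rs, τ = Rs·Cm).
* **The online measurement battery**: OLS slope, sliding maximum slope,
  peak, average, area, 10–90 % rise time, decay time, half-width,
  chord-referenced population-spike amplitude, input resistance, and series
  resistance by 1- or 2-exponential fit with back-extrapolation.

## A worked LTP experiment

The shipped `ltp_perfusion` protocol perfuses ACSF during baseline, switches
to a CaMKII-inhibitor solution, delivers a 100-pulse train, washes out, and
delivers a second train:

```r
library(perfusim)

rig <- fixture_rig("slice")                 # Slow0 8-channel controller, Port1
rig$slice <- slice_model(rng_seed = 42)     # reproducible trace noise

script <- fixture_protocol("ltp_perfusion")
rec <- run_protocol(script, rig, controls = list(
  control_event("uncheck_loop", after_sweep = 3, loop_index = 1)))
rec
#> <experiment_record> 32 sweep(s), 4 perfusion event(s), 6 valve action(s), 968.2 s simulated

sim <- simulate_slice_experiment(rec, rig)
sim$trains
#>   time_s sweep_name inhibitor_conc potentiated
#> 1  332.2    T0sweep   0.9996830078       FALSE
#> 2  695.5    T0sweep   0.0003138259        TRUE
unlist(ltp_summary(sim))
#>        pre       post      ratio
#> -0.1535738 -0.2264538  1.4745607
```

The first train lands while the chamber inhibitor concentration is ~1.0, so
it induces nothing; the second train lands after washout (concentration
~0.0003) and potentiates the pathway. The measured post/pre slope ratio,
1.47, reflects the configured `ltp_factor` of 1.5 plus trace noise. The
experimental log shows the same story as an operator would read it:

```
[       0.0 s] Perfuse Slow0 Ch1 ACSF
[       0.0 s] Sweep P0sweep
...
[      90.6 s] Perfuse Slow0 Ch2 CaMKII Inhibitor
```

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/perfusim.R run experiment.proto \
  --rig inst/extdata/rigs/slice.yaml \
  --controls inst/extdata/controls_example.csv --out out/ --simulate
```

writing `experiment.log`, `timeline.csv` (every valve action), per-sweep
trace CSVs and `spreadsheet.csv` (per-sweep measurements).

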