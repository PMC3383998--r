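controllers:
  Fast0:
    line: Fast0
    mode: analog
    n_channels: 16
    volts_per_channel: 0.5
    valves_per_channel: 1
    port: AnalogOut1
    bit_base: 0
    valve_switch_time_ms: 4.0
    binary_convention: 8ch
    amplitude_units: channel
sweep_defs:
  P0sweep:
    name: P0sweep
    duration_ms: 3000.0
    sample_rate_hz: 1000.0
    s0_train: ~
    s1_train: ~
    ic0_steps: ~
    ic1_epochs:
      duration_ms:
      - 500.0
      - 1000.0
      - 500.0
      amplitude:
      - -1.0
      - -1.0
      - -1.0
  P1sweep:
    name: P1sweep
    duration_ms: 3000.0
    sample_rate_hz: 1000.0
    s0_train: ~
    s1_train: ~
    ic0_steps: ~
    ic1_epochs:
      duration_ms:
      - 500.0
      - 1000.0
      - 500.0
      amplitude:
      - -1.0
      - -1.0
      - -1.0
  T0sweep:
    name: T0sweep
    duration_ms: 3000.0
    sample_rate_hz: 1000.0
    s0_train: ~
    s1_train: ~
    ic0_steps: ~
    ic1_epochs:
      duration_ms:
      - 500.0
      - 1000.0
      - 500.0
      amplitude:
      - -1.0
      - -1.0
      - -1.0
  T1sweep:
    name: T1sweep
    duration_ms: 3000.0
    sample_rate_hz: 1000.0
    s0_train: ~
    s1_train: ~
    ic0_steps: ~
    ic1_epochs:
      duration_ms:
      - 500.0
      - 1000.0
      - 500.0
      amplitude:
      - -1.0
      - -1.0
      - -1.0
scheme:
  Fast0: standard
tubing: []
flow_rate_ml_min: 2.0
chamber_volume_ml: 1.0
inter_sweep_interval_s: 5.0
flush_duration_s: 10.0
slow_port_jitter_ms: 0.0
biology:
  slice: ~
  patch:
    Emax: 500.0
    EC50: 10.0
    hill_h: 1.5
    Ki: 5.0
    tau_on_ms: 50.0
    tau_off_ms: 100.0
    Rin_MOhm: 150.0
    Rs_MOhm: 10.0
    Cm_pF: 30.0
    rs_second: ~
    noise_sd: 2.0
    rng_seed: ~
stepper: ~
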