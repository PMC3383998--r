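# Sequential LTP script: once the baseline loop is unchecked, the rest of
# the stimulation runs without the operator: a train, 11 single-pulse
# sweeps, a second train, and 8 closing single-pulse sweeps.
MainProtocol
  Loop 99999 continuous
    P0sweep
  EndLoop
  T0sweep
  Loop 11
    P0sweep
  EndLoop
  T0sweep
  Loop 8
    P0sweep
  EndLoop
EndProtocol
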