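# Circular baseline script: single-pulse sweeps repeat continuously and the
# operator evokes each induction train manually (single_sweep control).
MainProtocol
  Loop 99999 continuous
    P0sweep
  EndLoop
EndProtocol
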