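# Third linked protocol: antagonist 3 continuously on channel 3,
# agonist+antagonist solutions on channels 12-15 during sweep epochs.
# Across the three linked protocols, 15 distinct solutions are applied.
MainProtocol
  Perfuse Fast0 3
  Delay 30
  Loop 3
    P0sweep
    P1sweep
    T0sweep
    T1sweep
  EndLoop
EndProtocol

[labels]
Fast0 3 = Antag3
Fast0 12 = Antag3+Ag1
Fast0 13 = Antag3+Ag2
Fast0 14 = Antag3+Ag3
Fast0 15 = Antag3+Ag4

[sweeps]
P0sweep ic1 = -1 12 -1
P1sweep ic1 = -1 13 -1
T0sweep ic1 = -1 14 -1
T1sweep ic1 = -1 15 -1
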