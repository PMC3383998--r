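# Second linked protocol: antagonist 2 continuously on channel 2,
# agonist+antagonist solutions on channels 8-11 during sweep epochs.
MainProtocol
  Perfuse Fast0 2
  Delay 30
  Loop 3
    P0sweep
    P1sweep
    T0sweep
    T1sweep
  EndLoop
EndProtocol

[labels]
Fast0 2 = Antag2
Fast0 8 = Antag2+Ag1
Fast0 9 = Antag2+Ag2
Fast0 10 = Antag2+Ag3
Fast0 11 = Antag2+Ag4

[sweeps]
P0sweep ic1 = -1 8 -1
P1sweep ic1 = -1 9 -1
T0sweep ic1 = -1 10 -1
T1sweep ic1 = -1 11 -1

[link]
next = linked_antag3.proto
autostart = true
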