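# First of three linked single-line protocols (loosely bound antagonist:
# every agonist solution also contains the antagonist). Antagonist 1 is
# perfused continuously via channel 1; agonist+antagonist solutions on
# channels 4-7 are applied during the middle sweep epochs, three passes.
MainProtocol
  Perfuse Fast0 1
  Delay 30
  Loop 3
    P0sweep
    P1sweep
    T0sweep
    T1sweep
  EndLoop
EndProtocol

[labels]
Fast0 1 = Antag1
Fast0 4 = Antag1+Ag1
Fast0 5 = Antag1+Ag2
Fast0 6 = Antag1+Ag3
Fast0 7 = Antag1+Ag4

[sweeps]
P0sweep ic1 = -1 4 -1
P1sweep ic1 = -1 5 -1
T0sweep ic1 = -1 6 -1
T1sweep ic1 = -1 7 -1

[link]
next = linked_antag2.proto
autostart = true
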