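# Single-line fast perfusion: each antagonist is perfused continuously via
# channels 1-4 while four agonist concentrations (channels 5-8) are applied
# for 1 s during the middle epoch of the four sweeps. The -1 epochs hold
# the ongoing antagonist channel.
MainProtocol
  Perfuse Fast0 1
  Delay 30
  P0sweep
  P1sweep
  T0sweep
  T1sweep
  Perfuse Fast0 2
  Delay 30
  P0sweep
  P1sweep
  T0sweep
  T1sweep
  Perfuse Fast0 3
  Delay 30
  P0sweep
  P1sweep
  T0sweep
  T1sweep
  Perfuse Fast0 4
  Delay 30
  P0sweep
  P1sweep
  T0sweep
  T1sweep
EndProtocol

[labels]
Fast0 1 = Antagonist 1
Fast0 2 = Antagonist 2
Fast0 3 = Antagonist 3
Fast0 4 = Antagonist 4
Fast0 5 = Agonist 1
Fast0 6 = Agonist 2
Fast0 7 = Agonist 3
Fast0 8 = Agonist 4

[sweeps]
P0sweep ic1 = -1 5 -1
P1sweep ic1 = -1 6 -1
T0sweep ic1 = -1 7 -1
T1sweep ic1 = -1 8 -1
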