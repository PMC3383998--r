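# Triple-line stepper protocol. Slow1 feeds antagonist-only solutions to
# Tube1, Slow0 feeds agonists 1-2 to Tube0, Fast1 feeds agonists 3-4 to
# Tube2. The Fast0 stepper rests on Tube1 (channel 1) between sweeps and
# momentarily moves to Tube0 (P0sweep middle epoch, channel 0) or Tube2
# (P1sweep middle epoch, channel 2), twice per agonist.
MainProtocol
  Perfuse Slow1 1
  Perfuse Fast0 1
  Perfuse Slow0 1
  P0sweep
  P0sweep
  Perfuse Slow0 2
  P0sweep
  P0sweep
  Perfuse Fast1 1
  P1sweep
  P1sweep
  Perfuse Fast1 2
  P1sweep
  P1sweep
  Perfuse Slow1 2
  Perfuse Slow0 1
  P0sweep
  P0sweep
  Perfuse Slow0 2
  P0sweep
  P0sweep
  Perfuse Fast1 1
  P1sweep
  P1sweep
  Perfuse Fast1 2
  P1sweep
  P1sweep
EndProtocol

[labels]
Slow1 1 = Antag1
Slow1 2 = Antag2
Slow0 1 = Ag1
Slow0 2 = Ag2
Fast1 1 = Ag3
Fast1 2 = Ag4
Fast0 0 = Tube0
Fast0 1 = Tube1
Fast0 2 = Tube2

[sweeps]
P0sweep ic1 = -1 0 -1
P1sweep ic1 = -1 2 -1
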