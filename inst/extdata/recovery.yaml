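# Recovery scenario: weak production for everything except AKT, starting
# near the homeostatic pattern (all off, AKT on).
defaults: {beta: 0.3, gamma: 1.0, x0: 0.05, theta: 0.5, h: 8}
species:
  AKT: {beta: 1.2, x0: 0.9}
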