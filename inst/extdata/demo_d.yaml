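# Inhibition scenario: ERK and GLUT-1 held back by weak production,
# restraining OGT, VEGF and HIF-1 in an intermediate state.
defaults: {beta: 0.4, gamma: 1.0, x0: 0.1, theta: 0.5, h: 8}
species:
  ERK:    {beta: 0.2, x0: 0.25}
  GLUT-1: {beta: 0.25, x0: 0.35}
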