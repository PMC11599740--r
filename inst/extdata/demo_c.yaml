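# Hyperactivation of ERK and GLUT-1: slow ERK turnover sustains HIF-1,
# driving GLUT-1, OGT and VEGF into the aggressive regime.
defaults: {beta: 1.0, gamma: 1.0, x0: 0.1, theta: 0.5, h: 3}
species:
  ERK:    {beta: 0.8, gamma: 0.5, x0: 0.9}
  GLUT-1: {x0: 1.0}
  HIF-1:  {x0: 0.6}
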