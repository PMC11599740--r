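# Pathogenic scenario: start near the logical deadlock pattern
# (HIF-1, ERK, VEGF, p53, b-catenin, GLUT-1, C-MYC, OGT high; AKT low).
defaults: {beta: 1.0, gamma: 1.0, x0: 0.0, theta: 0.5, h: 8}
species:
  HIF-1:     {x0: 0.9}
  ERK:       {x0: 0.9}
  VEGF:      {x0: 0.9}
  p53:       {x0: 0.9}
  β-catenin: {x0: 0.9}
  AKT:       {x0: 0.05}
  GLUT-1:    {x0: 0.9}
  C-MYC:     {x0: 0.9}
  OGT:       {x0: 0.9}
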