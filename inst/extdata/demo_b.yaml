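# VEGF/ERK/HIF-1 pulse: a transient rise of VEGF and HIF-1 followed by
# decay toward near-zero, with ERK degrading more slowly than VEGF.
defaults: {beta: 0.15, gamma: 0.8, x0: 0.0, theta: 0.5, h: 8}
species:
  HIF-1:  {x0: 0.8}
  C-MYC:  {x0: 0.8}
  VEGF:   {beta: 0.5, gamma: 0.9, x0: 0.1}
  ERK:    {beta: 0.1, gamma: 0.12, x0: 0.1}
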