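# Perturbation of the three guardians: p53, b-catenin and AKT start high,
# every other species at zero concentration.
defaults: {beta: 0.6, gamma: 0.8, x0: 0.0, theta: 0.5, h: 8}
species:
  p53:       {x0: 0.31}
  β-catenin: {x0: 0.8}
  AKT:       {x0: 0.8}
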