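# Conventional and invariant PMF of V = x^2 along the erf CV at beta = 1.
stage: pmf
seed: 1
beta: 1
D: 1
surface: quadratic1d
pmf:
  map: erf1d
  grid:
    from: -0.95
    to: 0.95
    n_points: 101
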