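# Ground-truth analysis: MFEP in (x, y), Euclidean arc length, G = V,
# constant D = kBT.  kBT must be stated explicitly (kcal/mol, 300 K).
stage: pipeline
pipeline: [mfep, discretize, mfpt]
seed: 1
kBT: 0.596
D: 0.596
surface:
  id: muller_brown
  alpha: 0.1
metric: euclidean
mfep:
  endpoints:
    - [-0.56, 1.44]
    - [0.62, 0.03]
  n_images: 20
  tol: 1.0e-8
discretize:
  n_bins: 1000
  smooth: true
mfpt:
  bin_A: 1
  bin_B: 1000
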