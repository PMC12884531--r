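# Riemannian analysis of the log-polar path: identical setup to case 2
# (constant D with metric h = exp(2X)); the generator is identical by
# construction, so this config differs from case 2 only in name.
stage: pipeline
pipeline: [mfep, discretize, mfpt]
seed: 1
kBT: 0.596
D: 0.596
surface:
  id: muller_brown
  alpha: 0.1
metric: euclidean
h_metric: logpolar
mfep:
  endpoints:
    - [-0.56, 1.44]
    - [0.62, 0.03]
  n_images: 20
  tol: 1.0e-8
discretize:
  n_bins: 1000
  smooth: true
  transform: logpolar
mfpt:
  bin_A: 1
  bin_B: 1000
  inverse_transform: logpolar
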