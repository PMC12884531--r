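# Synthetic periodic 2-well surrogate: simulate, bin along a 20-center
# path, count lagged transitions, fit (G, h) by maximum likelihood and
# compute the MFPT from the fitted profile.
stage: pipeline
pipeline: [simulate, mfep, discretize, count, fit, mfpt]
seed: 1
beta: 1
D: 1
surface: synthetic_dipeptide
metric: euclidean
simulate:
  dt: 0.01
  n_steps: 120000
  x0: [0.2, 0.0]
mfep:
  endpoints:
    - [0.2, 0.0]
    - [2.9, 0.0]
  n_images: 20
  tol: 1.0e-8
discretize:
  n_bins: 20
  periodicity: [6.283185307179586, 6.283185307179586]
count:
  lag_steps: 10
  mode: sliding
fit:
  max_iter: 2000
mfpt:
  from_profile: true
  bin_A: 1
  bin_B: 20
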