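---
title: "Invariant thermodynamics and kinetics on collective-variable spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant thermodynamics and kinetics on collective-variable spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemcv)
```

## The problem: PMFs are not coordinate-invariant

A collective variable (CV) $\xi(x)$ compresses a high-dimensional
configuration $x$ into a few smooth coordinates.  The conventional
potential of mean force along a CV,
$$\tilde A(\zeta) = -\beta^{-1}\log\left\langle\delta(\zeta - \xi(x))\right\rangle,$$
depends on how the coordinate is stretched: for a 1D system with
potential $V(x)$ and a strictly increasing CV with inverse
$\eta = \xi^{-1}$,
$$\tilde A(\zeta) = V(\eta(\zeta)) - \beta^{-1}\log\eta'(\zeta),$$
so the *shape* of the profile — positions of minima, apparent barrier
heights — changes under reparameterization.  The canonical
demonstration is $V(x) = x^2$ at $\beta = 1$: along $\xi = \mathrm{erf}(x)$
the conventional PMF is exactly constant, $\log(2/\sqrt\pi) \approx 0.1208$,
even though the underlying system is a harmonic well.  Conversely, by
solving the ordinary differential equation
$$\frac{d\zeta}{dx} = \exp\!\big(\tilde A(\zeta) - V(x)\big)$$
(`design_cv_for_pmf()`) one can manufacture a CV whose conventional PMF
equals *any* prescribed profile — an inverted parabola, a rapid
oscillation — for the same harmonic system.

The resolution is geometric.  The CV gradients induce a metric on CV
space, $g^{-1}_{ij} = \nabla\xi_i\cdot\nabla\xi_j$ (here estimated
pointwise from Jacobians, or per histogram bin as a conditional
average), and the invariant PMF
$$A(\zeta) = \tilde A(\zeta) + \tfrac{1}{2\beta}\log\big(g(\zeta)/g_0\big)$$
is unchanged under smooth reparameterization: projected back to $x$,
every monotone CV yields the same curve $V(x)$.  The package provides
both the analytic 1D route (`conventional_pmf_1d()`,
`invariant_pmf_1d()`) and a histogram estimator with the metric
correction (`histogram_pmf()`).

### Numerical choices in the PMF module

* **CV-design ODE.** The defining relation is usually written as an ODE
  for the inverse map, $d\eta/d\zeta = \exp(-\tilde A + V(\eta))$, whose
  right-hand side diverges super-exponentially at the edge of the
  realizable CV interval.  The package integrates the equivalent ODE in
  the configuration variable (shown above), where the solution merely
  *saturates* at that edge, using `deSolve::lsodar` (relative/absolute
  tolerance $10^{-8}/10^{-12}$) with root-based stopping when $\zeta$
  leaves the requested grid.  This keeps tabulation accuracy uniform up
  to the boundary; the map is returned as a monotone
  (Hyman-filtered) spline whose derivative serves as the Jacobian, so
  round-trip checks measure genuine interpolation error rather than an
  algebraic identity.  Truncated targets signal a
  `riemcv_domain_truncation` warning carrying the reachable interval.
* **Histogram conventions.** Bins are half-open $[lo, hi)$ with the
  rightmost bin closed; empty bins are masked; profiles are shifted by
  one common constant (conventional minimum to zero) so the per-bin
  identity between the two profiles is preserved exactly.  In one
  dimension the bin metric is $g^{-1/2} = \langle|\xi'|\rangle_{bin}$;
  in $d>1$ the inverse-metric *matrix* is averaged per bin and the
  determinant taken afterwards.

## Diffusion on a curved CV space

If the projected dynamics are diffusive, the coordinate-consistent
overdamped Langevin equation on the CV manifold is
$$d\zeta = -\big(\beta D\, g^{-1}\nabla A + b\big)\,dt + \sqrt{2D}\,dW,
\qquad b_i = -D\, g^{jk}\Gamma^i_{jk},$$
with Christoffel symbols $\Gamma$ of the metric and a Wiener process
whose covariance is $g^{-1}$.  `simulate_overdamped()` integrates this
with explicit Euler–Maruyama steps, all coefficients frozen at the
step's start point (Itô convention); the identity metric reduces
bitwise to the flat-space integrator.  Christoffel symbols come from
registered analytic metric derivatives when available, otherwise from
central differences with step $10^{-4}$ in CV units
(`christoffel_drift()`).  A useful structural check: for a conformal 2D
metric $e^{2X} I$ (the log-polar plane) the contraction
$g^{jk}\Gamma^i_{jk}$ vanishes identically, so the drift is zero even
though the space is curved.

The simulator doubles as the package's synthetic-data generator.  It
emulates equilibrium, memoryless diffusion on an analytic surface with
a known metric — which is exactly the model class the estimators
assume.  It does **not** emulate inertial dynamics, thermostat
artifacts, or the memory effects of projecting real molecular dynamics
onto a CV; tests passing on these data certify the discretization and
estimation machinery, not robustness to non-Markovian trajectories.

## Paths, rate matrices and their inversion

Kinetics along a transition path are reduced to a 1D Smoluchowski
equation in a path parameter $r \in [0, 1]$ endowed with a scalar
metric, $ds^2 = h(r)\,dr^2$.  `reparameterize()` spaces bin centers
uniformly in metric arc length (segment lengths evaluated with the
metric at segment midpoints; optionally after a natural-spline
smoothing of a coarse input polyline, recommended when the input is a
20-image string), and `string_mfep()` finds the minimum free energy
path as the zero-temperature string: steepest descent along the
invariant gradient $g^{-1}\nabla A$ alternated with re-spacing, fixed
step $\gamma = 0.01\,L/\max|g^{-1}\nabla A|$, endpoints relaxed to
their minima first.  The discrete string's fixed point satisfies the
parallel-gradient condition only up to a resolution artifact of order
(curvature $\times$ spacing$^2$); the tests verify that this residual
shrinks quadratically with the number of images rather than asserting
an absolute threshold.

The finite-volume discretization of the metric Smoluchowski equation
(density per unit $r$, stationary law $\sqrt h\, e^{-\beta G}$) gives
the tridiagonal generator
$$R_{n,n\pm1} = \frac{D}{\delta r^2\sqrt{h_{n\pm1}\,h_{n\pm1/2}}}
  \exp\!\Big(-\tfrac\beta2 (G_n - G_{n\pm1})\Big),$$
columns summing to zero, reflective ends, and midpoints interpolated by
$1/\sqrt{h_{n+1/2}} = \tfrac12(1/\sqrt{h_n} + 1/\sqrt{h_{n+1}})$.  Two
placements of the node metric ($h_n$ vs $h_{n\pm1}$, the source node)
appear superficially plausible; only the source-node form makes the
matrix first-passage times converge to the closed-form double
quadrature and the profile recovery an exact inverse, which is how the
package fixes the convention (the alternative misestimates the
stationary law by $1/h$ and fails the cross-method check by a factor
of two on curved paths).

The same physics can be bookkept conventionally as a position-dependent
diffusion profile $D(r) = D/h(r)$ acting with a conventional free
energy.  `build_rate_matrix_conventional()` converts those inputs
*exactly* to the invariant pair and reuses the single builder, so the
two analyses produce entrywise-identical generators, propagators and
MFPTs — the equivalence is structural, not numerical.  The historical
per-node-diffusion form $R_{n,m} = (D_n + D_m)/(2\delta r^2)\cdot
\exp(-\beta(G_n - G_m)/2)$ is also provided (scheme `"midpointD"`); it
coincides with the riemannian scheme for constant $D$ but differs at
first order in $\Delta\log h$ per bond otherwise, which is why the
conversion route, not the arithmetic-mean form, realizes the exact
equivalence.

### Recovering $G$ and $h$ from rates

Detailed balance ties free-energy differences to rate ratios and the
midpoint metric to rate products,
$$h_{n+1/2} = \frac{D^2}{\delta r^4\,\sqrt{h_n h_{n+1}}\,
  R_{n,n+1} R_{n+1,n}}.$$
`profiles_from_rates()` implements two inversions.  The *pairwise* mode
iterates the midpoint relation with node re-interpolation to a fixed
point (tolerance $10^{-10}$, second-order end extrapolation) and then
accumulates $G$ from the ratios using the converged metric; its
accuracy is second order in the per-bond variation of $\log h$.  The
*joint* mode is the exact inverse: given the scale gauge $h_1$ (with
$D$ fixed the inversion has exactly a one-parameter solution family),
it marches along the chain solving one monotone scalar equation per
bond by safeguarded Newton.  A global damped-Newton solve over all
$2(N-1)$ equations would find the same root; the marching form was
chosen because it is unconditionally stable, exactly sequential, and
each step has a provably monotone residual, making failure modes
transparent.

### Likelihood estimation from lagged transitions

Counting trajectory transitions $i \to j$ at a lag $\Delta t$ gives a
multinomial likelihood through the propagator
$P = e^{R\Delta t}$: $\log L = \sum C_{ji}\log P_{ji}$.
`fit_rate_model()` maximizes this over $(G_{2..N}, \log h_{1..N})$ with
gauges $G_1 = 0$ and $D$ fixed, using L-BFGS-B with the *analytic*
gradient obtained from the spectral Fréchet derivative of the matrix
exponential (the generator is symmetrizable by detailed balance, so
its exponential and derivative are computed from one symmetric
eigendecomposition — also the implementation behind `propagate()`).
$G$ is initialized from empirical stationary counts, $h$ from 1; bins
never visited are flagged unidentifiable.

One estimation subtlety deserves emphasis: because the exact inversion
has the one-parameter $(G, h)$ family noted above, broken only by the
midpoint-interpolation closure, the *rough* component of $\log h$ is
very weakly identified from counts.  At realistic sample sizes this
appears as an alternating $\pm$ zigzag in $\hat h$ with a compensating
zigzag in $\hat G$.  The option `lambda_h` adds a smoothness penalty
$\lambda_h \sum_n (\Delta \log h_n)^2$; interpreting it as a Gaussian
prior, $\lambda_h = 1/(2s^2)$ encodes an expected per-bond variation
$s$ of $\log h$.  The reference analyses use $\lambda_h = 100$
($s \approx 7\%$), which suppresses the soft-mode noise without
measurably biasing smooth profiles; the default is 0 so that exactness
round trips are unaffected.  A flat-prior Metropolis sampler
(`sample_rate_posterior()`) is provided for credible intervals.

### Mean first passage times

`mfpt_quadrature()` evaluates the closed form for diffusion from a
reflective boundary at $r_A$ to an absorbing target at $r_B$,
$$\tau_{A\to B} = \frac1D \int_{r_A}^{r_B}\! d\rho\, \sqrt{h(\rho)}\,
  e^{\beta G(\rho)} \int_{r_A}^{\rho}\! d\sigma\, \sqrt{h(\sigma)}\,
  e^{-\beta G(\sigma)},$$
by nested trapezoids with exponent shifting (barriers of tens of kBT do
not overflow).  The metric enters as $\sqrt h$ in each integral — the
arc element — so $h \to c^2 h$ rescales $\tau \to c^2\tau$, which is
also the sharpest check distinguishing this form from a full-$h$
misreading.  `mfpt_matrix()` solves the absorbing-boundary linear
system on the same discretization, so the two routes share
discretization error and agree to $\lesssim 1\%$ at $2000$ bins on the
benchmark problems; both are always computed in the pipelines as a
cross-method control.

### Path-metric normalization and the benchmark MFPT values

Two normalizations of the scalar path metric circulate: $ds^2 = h\,dr^2$
(so $h$ has units of squared length per unit $r$) and $h = ds/dr$.  The
package's native convention is the first — it is the one under which
all internal identities (stationary law, quadrature/matrix agreement,
round-trip inversion) hold with $\sqrt h$ factors.  The benchmark
reference values asserted by the acceptance tests
($1.3\times10^6$ and $1.9\times10^6$ time units for the Mueller-Brown
two-basin transition at $k_BT = 0.596$ kcal/mol, $D = k_BT$, 1000 bins)
were established under the second normalization; they are reproduced
exactly by supplying $h = ds/dr$ values (a constant $L$ on the
arc-length path, $e^{X} L_{XY}$ on the log-polar path) to the native
machinery, which is how `scripts/acceptance.R` computes them.  The
ground-truth value reproduces to two significant figures
($1.293\times10^6$); the log-polar value computes to
$1.77\times10^6$, about 7% below its reference — consistent with the
residual difference between the regenerated zero-temperature string
and the original coarse pathway, which is not publicly available — and
correctly exceeds the ground-truth value (a nonoptimal parameterization
slows the apparent kinetics).

## The synthetic periodic surrogate

`synthetic_dipeptide()` is a fully periodic 2D surface
$$V(\phi,\psi) = \tfrac\Delta2(1-\cos 2\phi) +
 \tfrac c2 (1-\sin\phi)^2 + \tfrac k2 (1-\cos\psi)$$
emulating the topology of a dihedral-angle landscape: two wells along
$\phi$ joined by one low channel at $\phi = \pi/2$, with the antipodal
channel raised by $2c$ so that essentially no transitions take it (the
squared asymmetry term exists precisely because a linear one leaves
that channel only marginally suppressed, and wrong-channel crossings
masquerade as impossible long-range jumps under a tridiagonal
likelihood).  The defaults ($\Delta = 2.2$, $c = 2.5$, $k = 8$ in kBT,
$D = 1.5$, $dt = 0.01$) put the effective barrier near $1.4$ kBT: a
clear double well that still crosses a few hundred times in the
$5\times10^5$-step reference trajectory, because the inter-well
free-energy offset can only be pinned to $\sim 2/\sqrt{n_{\rm cross}}$
however good the estimator.  The reference analysis bins the
trajectory on a 20-center path spanning $\phi \in [-0.7, 3.85]$ at
$\psi = 0$ — deliberately extending beyond both minima so the end bins
do not swallow entire basins — and harvests $10^5$ transitions at a
lag of 5 steps as non-overlapping (strided) windows: overlapping
windows would span a fivefold shorter trajectory at the same count and
their dependence violates the independence assumption of the
likelihood.  Longer lags were rejected because the tridiagonal
discretization bias grows visibly with lag on this bin width.  What
this surrogate does not probe: non-separable $\phi$–$\psi$ coupling,
memory from projected fast degrees of freedom, and initialization
protocols of real sampling campaigns.

## Degenerate inputs and tie-breaking

Singular points of CV maps (the log-polar origin, guard radius
$10^{-12}$), rank-deficient Jacobians, non-SPD metrics, non-monotone
1D maps, zero-length paths, endpoints relaxing to the same minimum,
disconnected rate chains, and observed transitions of probability zero
all raise typed conditions (`riemcv_domain_error`,
`riemcv_degenerate_metric`, `riemcv_invalid_cv`, ...).  Bin assignment
breaks ties toward the lower index and wraps periodic dimensions by
minimum image.  The atan2 branch is $(-\pi, \pi]$.

## Problem sizes

The test and acceptance analyses use: 1000–2000 path bins for the
Mueller-Brown studies (20 string images, spline-upsampled); $10^6$
samples for histogram PMFs; $2\times10^6$ steps for the equilibrium-
variance check of the overdamped oscillator; $5\times10^5$ steps and
$10^5$ transition pairs for the likelihood-fit study; 50-bin models for
round-trip inversions.  These sizes were chosen so that each check's
statistical or discretization error sits well below the tolerance it
asserts.

## Known limitations

* The string method is zero-temperature and deterministic; it finds
  the MFEP of the supplied (free-)energy field, not a finite-
  temperature principal curve, and can converge to different saddles
  for endpoints in other basins.
* The tridiagonal model assumes Markovian nearest-neighbor kinetics at
  the chosen lag; on real projected dynamics the fitted profiles
  acquire a lag dependence that should be checked by rerunning the fit
  over a range of lags.
* Voronoi path cells are built in the CV coordinates (with periodic
  wrapping), not as slabs normal to the path tangent; for strongly
  curved paths the difference matters near the bends.
* No umbrella sampling, metadynamics or reweighting: all estimators
  assume unbiased equilibrium data.
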