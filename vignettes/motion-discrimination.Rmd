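---
title: "Traveling-wave motion discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling-wave motion discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticalwaves)
```

## The problem

Most neurons in primary visual cortex respond selectively to the direction
of a moving stimulus: their space-time receptive fields are non-separable.
Classical accounts build that selectivity from explicit transmission
delays. `corticalwaves` implements an alternative mechanism in which the
cortical tissue itself generates endogenous traveling waves whose speed
and direction are set by the geometry of lateral coupling, and a moving
stimulus is detected when its space-time signature resonates with those
waves. Opponent wiring — two excitatory populations competing through a
shared inhibitory pool — then suppresses false motion signals.

The package provides four models and the analysis machinery around them:

* the point (non-spatial) E-I Wilson-Cowan pair,
* the point E-I-E opponency circuit,
* their 1-D spatial continuum counterparts with shifted-Gaussian lateral
  coupling on a periodic domain, driven by drifting sinusoidal gratings,

plus equilibrium continuation with bifurcation detection, seeded
winner-take-all trial ensembles, spatiotemporal spectral analysis and
tuning curves.

## The models

The point E-I model is

$$\tau_e \dot U_e = -U_e + F(w_{ee} U_e - w_{ei} U_i - b_e + J),\qquad
  \tau_i \dot U_i = -U_i + F(w_{ie} U_e - w_{ii} U_i - b_i),$$

with the logistic rate function $F(v) = 1/(1+e^{-v})$ and a stimulus $J$
entering the excitatory population only. The E-I-E circuit duplicates the
excitatory population; $e_1$ and $e_2$ are *not* directly coupled and
interact only through the shared inhibitory pool, with differential drive
$J_{e1} = J + \Delta$, $J_{e2} = J - \Delta$. For $\Delta = 0$ the system
is exactly equivariant under the $e_1 \leftrightarrow e_2$ exchange, which
is why the symmetric equilibrium can only lose uniqueness through a
pitchfork.

The spatial versions replace each product $w\,U$ by $w\,V$ where $V$ is
the activity weighted by a normalized Gaussian kernel
$K(x) = \frac{1}{\sigma\sqrt{\pi}} e^{-(x-\delta)^2/\sigma^2}$
over the periodic domain. The inhibitory spread is three times the
excitatory spread, producing a Mexican-hat net coupling that destabilizes
the homogeneous state into a spatially periodic pattern; a small shift
$\delta$ of the excitatory kernel makes that pattern travel. The stimulus
is a drifting grating
$J(x,t) = \frac{\alpha}{2}(\cos(2\pi f_x x - 2\pi f_t t) + 1)$,
with negative $f_t$ denoting leftward motion.

## Parameters

All scalar constants live in a single `wc_params()` object:

| parameter | default | units | role |
|---|---|---|---|
| `w_ee, w_ei, w_ie, w_ii` | 12, 10, 10, 1 | — | coupling weights |
| `b_e, b_i` | 1.75, 2.6 | — | firing thresholds |
| `tau_e, tau_i` | 5, 10 | ms | population time constants |
| `sigma_e, sigma_i` | 0.05, 0.15 | mm | kernel spreads (1:3 ratio) |
| `delta` | 0.02 | mm | excitatory kernel shift |
| `alpha` | 1 | — | grating amplitude |
| `dx` | 0.01 | mm | spatial step |

Two reported assignments of the time constants circulate for this
configuration ($\tau_e = 5, \tau_i = 10$ versus the swap). The package
resolves the ambiguity empirically and encodes the consistent one: with
$\tau_e = 5,\ \tau_i = 10$ the quiescent state destabilizes through a
supercritical Hopf bifurcation at $J \approx 0.41$ and the limit cycle at
$J = 1$ runs at $\approx 20$ Hz, whereas the swapped assignment produces
no oscillation at $J = 1$ at all (the acceptance suite asserts both
facts). Weights, thresholds and kernel scales are used exactly as listed.

## Numerical choices

**Time integration.** Point models integrate with the Bogacki-Shampine
2(3) adaptive pair (`deSolve`, `method = "ode23"`) at absolute and
relative tolerances $10^{-6}$, resampled on a uniform grid. Two hot paths
use an in-package fixed-step RK4 instead: the trial-ensemble runner
(vectorized over all trials at once) and the field integrator (FFT-based
lateral input per stage, $dt = 0.1$ ms). At these step sizes the fastest
linearized rate of the models (about $0.6\,\mathrm{ms}^{-1}$) is resolved
with two orders of margin; the suite cross-checks the fixed-step field
path against an independent point-model integration through the
homogeneous reduction (agreement to $10^{-9}$) and checks that halving the
adaptive tolerances moves trajectories by less than $10^{-4}$.

**Equilibria.** Damped Newton with the analytic Jacobian, residual
tolerance $10^{-10}$; equilibria seed the continuation and are re-verified
at every accepted branch point.

**Continuation.** Pseudo-arclength with a secant predictor and a bordered
Newton corrector, so folds are traversed. Steps halve on corrector
failure, or when the corrected point strays further from the prediction
than the step length (which signals a jump onto another branch near a
singular point), and regrow after success up to `max_step = 0.1`.
Eigenvalues are matched between consecutive points by minimal distance to
avoid spurious crossings from reordering. Hopf points are bisected on the
real part of the leading complex pair to $|\mathrm{Re}\,\lambda| <
10^{-8}$; fold points are refined by Newton on the extended system
$[\,\mathrm{rhs};\ \det \mathrm{Jac}\,] = 0$; branch points (only possible
on the exchange-symmetric branch) are bisected along the branch.
Limit-cycle envelopes are measured by direct simulation from a perturbed
equilibrium rather than by cycle continuation: the quantities of interest
are onsets and envelopes, which simulation yields at a fraction of the
engineering cost, and the near-onset envelope is checked against the
supercritical normal form ($\mathrm{width}^2$ linear in $J$, $R^2 >
0.95$).

**Winner scoring.** A trial's winner is the excitatory population with the
larger post-transient peak-to-trough range; flat pairs fall back to
comparing means. Outcomes within 10% relative of each other are counted
`undecided` and reported separately rather than silently assigned —
finite integration can end near the separatrix. Trials run 1000 ms with a
500 ms transient discard ($\ge 10$ periods of the $\approx 20$ Hz cycle,
enough for the attracting branch to be classified); the ensemble draws all
initial conditions uniformly on $[0,1]^3$ in a single seeded block, so a
`(seed, n)` pair is bit-reproducible. The 99% confidence half-width uses
the normal approximation ($z = 2.576$). `sudden` onset applies the full
stimulus from $t = 0$; `ramped` grows it linearly over 500 ms — the
minimal ramp consistent with "slowly ramped" — and the two protocols
genuinely differ: a weak bias yields about a quarter false positives under
sudden onset and none under ramping.

**Kernel orientation and the direction convention.** The discretized
kernel places its peak at $x = +\delta$ and is renormalized so its weights
sum to $1/dx$ (a uniform field is a fixed point of the convolution). The
field equations evaluate lateral input as circular *cross-correlation*
(equivalently, convolution with the reflected kernel): under this
orientation a positive shift tunes the layer to leftward motion, matching
the grating sign convention, and the e2 layer of the spatial opponency
model simply negates the shift. The orientation is pinned by tests: the
preferred leftward grating drives $U_{e1}$ across most of its dynamic
range while $U_{e2}$ stays below 0.01, and mirroring space while swapping
the layers maps solutions to solutions exactly.

**Spectral readouts.** Dominant spatiotemporal modes come from the 2-D
DFT of the mean-subtracted post-transient activity, excluding the
zero-frequency row and column; the representative with $f_x > 0$ is
reported and its temporal sign follows the grating convention (negative =
leftward). On commensurate synthetic plane waves recovery is exact, and
the suite asserts exactness, not approximation. Because a *static*
(Turing) pattern concentrates its power in the temporal-DC row that this
estimator deliberately excludes, the standing-wave readout
`dominant_spatial_frequency()` instead marginalizes the full 2-D spectrum
over temporal frequency, DC row included.

## The synthetic study conditions

No external data exist; every experiment is generated in code. The
defaults encode the study conditions: spatial runs start from the
homogeneous resting state plus a seeded uniform perturbation of amplitude
$10^{-3}$ per grid point (pattern formation from near-homogeneity is the
premise), the domain is $L = 4$ mm at $dx = 0.01$ mm — the length is a
modeling choice that fits exactly ten wavelengths of the reference
$f_x = 2.5$ cycles/mm grating, keeping stimulus and domain commensurate —
and gratings must hold an integer number of wavelengths (incommensurate
requests are rejected with the nearest valid value). Tuning curves sweep
one grating frequency at fixed seed and duration (2000 ms, response read
as the space-time maximum over the final half) with band edges defined by
half-maximum crossings, linearly interpolated; half-max is the standard
convention where no explicit criterion exists, and spatial sweep values
snap to multiples of $1/L$.

Problem sizes used by the shipped tests and the acceptance script:
ensembles of 300-4000 trials (99% CIs widen accordingly), 2000 ms field
simulations on 400 grid points, and a temporal tuning sweep of 0-40 Hz in
2 Hz steps.

What the generator does *not* emulate: biological noise (the dynamics are
deterministic; randomness enters only through initial conditions),
two-dimensional cortex, log-polar retinotopy, conduction delays, and
spiking. Passing tests therefore demonstrate properties of the
deterministic rate model under these idealized conditions, not of cortical
tissue.

## A known tension in the spatial pattern scale

With the parameters and kernel definition above, the symmetric-kernel
medium under uniform drive self-organizes a pattern at 3.25-3.5 cycles/mm
(robust across seeds, durations and onset protocols, and stable under
halving `dx`). This is internally consistent: the spatial Fourier
magnitude of the package's own Mexican-hat profile peaks at 3.25 cycles/mm
on the discrete mode grid, and linear stability analysis of the
homogeneous state puts the fastest-growing mode there too. The number
2.5 cycles/mm sometimes quoted for this configuration is *not* reproduced
by these equations; one acceptance check encodes that expectation and is
knowingly left failing rather than recalibrated, because every
grating-driven quantity (response ranges, direction selectivity, tuning
bands) verifies tightly with the kernels exactly as defined. Users probing
pattern scale should trust `mexican_hat()$dominant_fx` as the predictor of
what the simulation will actually select.

## Limitations

* One spatial dimension with periodic boundaries; mode quantization at
  multiples of $1/L$ produces genuine kinks in tuning curves.
* Limit cycles are characterized by simulation, not collocation; cycle
  stability is inferred from attraction, and codim-2 phenomena are out of
  scope.
* The undecided margin (10%), trial duration (1000 ms) and ramp shape
  (linear, 500 ms) are explicit conventions of this implementation, and
  ensemble percentages shift by fractions of a point under reasonable
  alternatives.
* Fixed-step field integration trades error control for speed; the step
  is validated for the default parameters, and users pushing weights or
  time constants far from them should re-check with `dt` halved.
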