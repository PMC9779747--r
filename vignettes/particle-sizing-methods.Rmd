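---
title: "Methods: sizing and counting small cellular particles by nanotracking and DLS"
author: "scpsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sizing and counting small cellular particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpsize)
```

# The problem

Sub-micron particles harvested from biological material — extracellular
vesicles, lipoproteins, protein aggregates, membrane fragments, liposome
preparations — are too small for direct light-microscopic sizing. Two
widely used optical routes infer their size from Brownian motion instead:

* **Single-particle nanotracking** (interferometric light microscopy,
  ILM/NTA family): individual particles are localized frame by frame in a
  known detection volume (~15 pL), their trajectories reconstructed, and
  each track's mean squared displacement (MSD) converted to a diffusion
  coefficient and then a hydrodynamic radius. Counting particles in the
  volume gives a number density, which batch methods cannot provide.
* **Dynamic light scattering** (DLS): intensity fluctuations of scattered
  laser light encode a distribution of exponential decay rates; a
  regularized inverse-Laplace inversion recovers an intensity-weighted
  size distribution for the whole ensemble at once.

Both routes share one physical model. A sphere of hydrodynamic radius
$R_h$ in a medium of viscosity $\eta$ at temperature $T$ diffuses with

$$D = \frac{k T}{6 \pi \eta R_h},$$

the Stokes–Einstein relation ($k$ = Boltzmann constant). Nanotracking
measures $D$ through $\langle d^2(\Delta t)\rangle = 4 D \Delta t$ for the
2-D projection of the motion; DLS measures it through the field-correlation
decay rate $\Gamma = q^2 D$, with scattering vector
$q = (4\pi n_0/\lambda_0)\sin(\theta/2)$. Everything downstream of these
two equations is estimation detail — and that detail is exactly where the
biases live that this package makes testable.

# The nanotracking chain

`msd_curve()` averages squared 2-D displacements over all overlapping
pairs at each lag; frames bridged over detection gaps contribute no
pairs. `diffusion_from_msd()` offers two estimators:

* **`lag1`**: $D = \mathrm{MSD}(\Delta t)/(4\Delta t)$. This is the
  textbook single-lag proportionality. Static localization error
  $\sigma_{loc}$ adds $4\sigma_{loc}^2$ to every MSD value, so `lag1`
  overestimates $D$ (and underestimates $R_h$) on noisy data.
* **`linear_fit`** (default): unweighted least squares of MSD against the
  first `fit_lags` lags (default 4) with a **free intercept**. The
  intercept absorbs the constant noise offset, leaving the slope — and
  hence $D = \mathrm{slope}/4$ — unbiased by localization error.

`ilm_summary()` runs this chain per track, inverts to a per-track $R_h$,
and reports the unweighted mean (and, for at least 40 contributing
tracks, the SD) across tracks, mirroring the per-sample
"N tracked, $R_h \pm$ SD" convention of multi-method characterization
tables. Tracks with non-positive $D$ estimates are excluded and tallied.
Number density is the time-average of per-frame detected counts divided
by the detection volume, corrected by the dilution factor; this estimator
is insensitive to track fragmentation. Quality flags follow the reporting
conventions of such tables: `UDL` (under detection limit) when fewer than
`udl_min_tracks` tracks could be sized (default 5 — instruments do not
publish their rule, so this is an explicit free parameter), `LP` when any
track exceeds 1 µm, `BA` as a pass-through annotation.

**A bias worth knowing about.** The per-track inversion $R_h = c/\hat D$
is convex in $\hat D$, so by Jensen's inequality the *mean* per-track
radius overshoots the true radius by roughly $\mathrm{CV}^2(\hat D)$.
With the default 4-lag fit this is about 10–16 % for 50-step tracks and
1.5–3 % for 300-step tracks. The package deliberately keeps the
per-track-then-average convention (it is what the instruments report);
analyses that need the bias small should use long tracks, as the
recovery tests here do (300-step tracks, where the measured recovery is
within a few nanometers of a 100 nm truth). Averaging $\hat D$ first and
inverting once avoids the bias but answers a different question.

# The DLS chain

`g1_from_g2()` applies the Siegert relation
$g_2(t) = 1 + \beta |g_1(t)|^2$ in reverse,
$g_1 = \sqrt{\max(0, (g_2-1)/\beta)}$, clipping and counting negative
radicands (baseline noise at long lags). If $\beta$ is unknown,
`estimate_beta()` extrapolates $\log(g_2-1)$ from the first five lags to
$t = 0$.

`invert_decay_spectrum()` solves the constrained regularized problem

$$\min_{w \ge 0} \; \|A w - g_1\|^2 + \lambda \|L w\|^2, \qquad
A_{jk} = e^{-\Gamma_k t_j},$$

on a log-spaced grid of at most 50 decay rates (default 50 points over 6
decades centered on the reciprocal lag range), with $L$ the
second-difference operator — the standard CONTIN-style formulation
(smoothness penalty rather than a plain ridge, matching that program's
behavior). The non-negative solver is Lawson–Hanson NNLS
(`pracma::lsqnonneg`) on the stacked system.

**Choosing $\lambda$.** With `reg_strength = "auto"` the solver scans a
logarithmic $\lambda$ grid ($10^{-6}$–$10^2$, 17 points) and keeps the
largest $\lambda$ whose residual norm stays within 20 % of the best
achievable — i.e. the most smoothing the data do not object to. An
L-curve corner criterion was evaluated first and rejected: under the
non-negativity constraint with true decay rates off the grid, the
residual floor is set by grid mismatch rather than noise and the
residual–seminorm curve has no usable corner; the chord-distance corner
then lands on heavy smoothing that merges well-separated populations. A
fixed numeric `reg_strength` (including 0) is retained for
reproducibility and for oracle tests.

`size_distribution()` maps each grid rate to a radius via
$D = \Gamma/q^2$; `peaks_from_distribution()` segments the weight vector
into contiguous runs (bins below $10^{-4}$ of the maximum weight count as
empty, which prevents noise bridges between peaks), reports each peak's
intensity-weighted mean radius and intensity fraction, drops peaks below
`min_fraction`, keeps at most four, and flags any peak beyond 10 µm as a
very-large-particle component. Reports list the highest-fraction peak as
the "main" population, with smaller/larger companions beside it.

# The synthetic generator

`simulate_tracks()` and `simulate_dls_g2()` provide ground-truthed input
with the statistical structure the inference stages assume — and with the
two mechanisms that break that structure in real isolates.

* **Geometry.** Particles live in a box of twice the detection volume
  (default detection volume 15 pL, a cube unless `field_extent` says
  otherwise) with the detection box centered inside it. The outer box
  has **reflecting walls**: this keeps the reservoir density stationary
  over arbitrarily long movies (with open outer boundaries the reservoir
  drains and number densities bias low by several percent over hundreds
  of frames). The walls are microns away from the detection volume, far
  beyond the few-lag displacement scale used for sizing, so detected
  displacement statistics are unaffected. Tracks still begin and end
  naturally as particles cross the detection boundary.
* **Counts.** The particle number per population is Poisson with mean
  (stock density / dilution factor) × simulation volume; per-frame
  in-volume counts then fluctuate around density × detection volume.
* **Detection.** Image formation is deliberately not modeled (the
  inference operates on tracks, not interferograms): detection is a
  Bernoulli event per frame with probability `detection_probability`,
  and observed positions are true 2-D projections plus Gaussian noise of
  SD `localization_noise_sd` per axis.
* **Ordinary diffusion.** Per-axis Gaussian steps of variance
  $2 D \Delta t$, with $D$ from the Stokes–Einstein relation (spheres)
  or a rigid-rod formula (below).
* **Subdiffusion** (the filament-obstruction mechanism): fractional
  Brownian motion per axis with Hurst exponent $H = \alpha/2$, scaled so
  the 2-D MSD is exactly $4 K \Delta t^\alpha$. Sampling is exact, via
  the Cholesky factor of the fBm covariance (affordable because tracks
  are at most a few hundred frames; the factor is computed once per
  population). When `K` is omitted it is chosen to match the lag-1 MSD
  of free diffusion at the stated radius, which isolates the estimator's
  lag dependence as the only difference between matched populations.
* **Rod-shaped diffusers** (the non-globular-particle mechanism): the
  orientation-averaged translational coefficient of Tirado and García de
  la Torre, $D = kT(\ln p + \nu)/(3\pi\eta L)$ with $p = L/d$ and end
  correction $\nu = 0.312 + 0.565/p + 0.100/p^2$ — a standard choice for
  rigid rods of moderate aspect ratio; its value always lies between the
  bounding spheres of radii $L/2$ and $d/2$ and approaches the
  equal-volume sphere as $p \to 1$.
* **Correlograms.** $g_1(t) = \sum_i w_i e^{-q^2 D_i t}$ with Rayleigh
  intensity weights $w_i \propto \rho_i R_{h,i}^6$ (an explicit,
  configurable choice — instruments do not publish their weighting;
  Rayleigh is the correct small-particle limit and makes the classic
  point that DLS intensities are dominated by the largest particles),
  then $g_2 = 1 + \beta g_1^2$ plus additive zero-mean Gaussian noise of
  SD `noise_sd` × β per lag (`noise_sd` is specified relative to the
  Siegert intercept amplitude).

What the generator does **not** emulate: optical point-spread functions
and interference patterns, size-dependent detection efficiency (detection
probability is size-independent; instruments' density estimates may not
be), polydispersity within a mode, inter-particle interactions,
multiple scattering, number fluctuations in the DLS scattering volume,
and rod rotational-translational coupling in DLS (rod modes are rejected
there). Passing tests therefore demonstrate correctness of the inference
chain under its own assumptions, not instrument fidelity on real
samples.

# Track linking

Nanotracking operates in the dilute regime: typical inter-particle
spacing at hundreds of particles per 15 pL is several micrometers, while
per-frame steps are fractions of a micrometer. `link_localizations()`
therefore uses distance-gated greedy assignment: per frame, candidate
(track, localization) pairs within `max_displacement` are accepted in
order of increasing distance (ties: older track first), each side used
at most once; tracks may bridge up to `max_gap` missed frames.
Input rows are canonically sorted first, so linking is invariant to row
order. On well-separated simulated data the recovered partition equals
the generator's exactly (Rand index 1 in the test suite). A physically
motivated default gate is `default_max_displacement()`: five times the
RMS frame-to-frame displacement of the fastest plausible particle class.
Probabilistic multi-hypothesis or global-cost linking is out of scope.

# Comparison arithmetic

The cross-method stage is deliberately plain arithmetic, kept exact and
unit-tested because published tables are derived from it:

* `dilution_ratio()` — ratio of dilution-corrected quantities measured
  at two dilutions (ideally 1); displayed half-up at 2 decimals, full
  precision retained. The half-up rounding includes a $10^{-9}$ guard so
  decimal literals on a half boundary round the way a human expects.
* `replicate_error()` — mean, largest absolute deviation from the mean,
  and that deviation as a percentage: the conservative replicate-error
  convention used with triplicate instrument runs.
* `agreement_within_error()` / `agreement_tally()` — two measurements
  agree when $|a - b| \le \mathrm{err}_a + \mathrm{err}_b$; the tally is
  generic over user-supplied pairs rather than hard-coding any
  particular sample list, because published error estimates rarely cover
  every sample one-to-one.
* `emit_summary_tables()` — fixed-layout TSVs with empty cells for
  missing values, so reports mirror the familiar table structure.

The package bundles a study-style measurement dataset
(`study_summary_path()`): per-sample multi-method measurements for
isolates from blood preparations, spruce-needle homogenate, microalgal
flagella suspensions and conditioned media, and liposome preparations at
two dilutions. Cells that are textual in the source ("~1000", multi-value
entries, under-detection-limit marks) are kept as text; only numerically
clean columns are parsed as numbers.

# Numerical choices and degenerate inputs

* All internal computation is SI (meters, seconds); files use nanometers
  and seconds; configuration files use nm/pL/per-mL.
* The fBm covariance receives a $10^{-12}$-relative diagonal jitter
  before factorization to guard against numerically semi-definite
  matrices.
* Negative Siegert radicands clip to zero and are counted, never
  silently dropped.
* Non-positive diffusion estimates propagate as flags (`nonphysical`)
  and exclusion tallies rather than errors: degenerate tracks are data,
  not bugs.
* An all-zero $g_1$, rod modes in DLS synthesis, non-increasing lag
  grids, aspect ratios ≤ 1 and out-of-range angles are errors.
* The Siegert round trip is exact to $10^{-12}$ wherever $g_2 - 1$ is
  not dominated by double-precision cancellation (i.e. $g_1 \gtrsim
  10^{-3}$); beyond that the reconstruction error is
  $\varepsilon/(2\beta g_1)$ by construction of floating-point
  arithmetic.

# Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which the statistical claims are
comfortably inside their bands: radius/density recovery uses a 100 nm
monodisperse population at a mean of 800 particles in 15 pL, 301 frames
at $\Delta t$ = 10 ms, tracks filtered to full length (≥ 300 tracks ×
300 steps); bias runs use 101 frames at a mean of 400–500 particles;
DLS runs use 200 log-spaced lags over $10^{-6}$–$1$ s and the default
50-point rate grid; the dilution-consistency experiment uses 10 seed
pairs at 25 frames. Identity and arithmetic checks are instantaneous.

# Known limitations

* Sphere-based sizing applied to rods or obstructed motion returns a
  biased equivalent radius by design — that is the phenomenon under
  study, and the direction of both biases is asserted in the tests
  (apparent radius grows with the fit window under subdiffusion; rods
  map to an equivalent sphere between their bounding radii).
* Under measurement noise the regularized inversion merges populations
  closer than about a decade in size, as constrained-regularization
  methods generally do; the resolution claims in the tests are for
  noiseless curves.
* The intensity weighting ($R_h^6$) ignores Mie corrections, which
  matter for particles approaching the wavelength.
* Number density is not corrected for size-dependent detectability;
  published instrument densities may embed such corrections.
* The linker is greedy; at densities where inter-particle spacing
  approaches the per-frame step it will mislink, and no global
  assignment fallback is provided.
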