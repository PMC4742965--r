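---
title: "Models and methods behind beadtaxis"
author: "beadtaxis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beadtaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadtaxis)
```

## The assay

Benthic pennate diatoms glide over surfaces by secreting adhesive polymers
through the raphe, and silicic acid (dSi) — the substrate of their cell
wall — is frequently the resource that limits their growth. The bead assay
quantifies whether starved cells can locate a local dSi hotspot: an
aluminium-oxide particle loaded with silicate is placed in a shallow
chamber, a diffusion gradient develops around it, and cell behaviour is
recorded for 600 s at 1 frame per second. The field of view is divided
into three concentric annuli of 112 µm width (bins A–C) centred on the
bead, giving a 336-µm observation radius and a counting area of
π·(336 µm)² ≈ 0.355 mm². All package metrics are reported per bin on this
layout (`bead_geometry()`, `radial_bin()`).

Bin boundaries are half-open and lower-inclusive (a cell exactly at
112 µm belongs to bin B), and positions on the bead itself count as bin A,
because cells physically contact the particle. Distances are continuous
physical positions in µm; no pixel semantics are retained — readers accept
an optional calibration factor for pixel-unit exports.

## The bead as a point source

The bead is modelled as a constant point source with flux *i* (mol s⁻¹)
in a medium with molecular diffusivity *D* (cm² s⁻¹). Two steady-state
profiles are implemented (`point_source_gradient()`):

* the **flat-chamber form** `C(r) = i / (4π √r D)`, with *r* in cm and the
  result read as mol cm⁻³. The √r factor corrects the profile shape for a
  quasi-two-dimensional chamber. With the measured flux
  *i* = 1.21×10⁻¹³ mol s⁻¹ and *D* = 10⁻⁵ cm² s⁻¹ it gives ≈5 µM at the
  336-µm field edge, matching the concentration measured there. This is
  the default, because it is the form the assay was calibrated with.
* the **spherical point-source form** `C(r) = i / (4π D r)`, the textbook
  3-D solution, provided as a physically standard alternative.

Every profile table and report labels which variant produced it. The two
differ substantially (≈29 µM vs ≈5 µM at the edge), and the flat-chamber
form is dimensionally anomalous if read strictly — we keep it because it
reproduces the calibrated edge value, and we do not assert any particular
value at the bead surface, where neither form is reliable (the
concentration "at the surface" depends on a choice of radius that the
assay does not pin down).

Supporting quantities: the equilibration time is taken as `d²/D` for a
field diameter *d* (672 µm → ≈452 s, `time_to_steady_state()`); the
released fraction over an assay is `min(1, i·t/L)` for loading *L*
(1.4 nmol → ≈5% in 600 s, `fraction_released()`); per-particle loading
follows the preparation arithmetic
`volume × concentration / (mass × particles mg⁻¹)` (`bead_loading()`).
Particle counts per mg are an input rather than a constant: published
counts (≈2,640 ± 660 mg⁻¹) and published per-particle loadings are not
exactly mutually consistent, and we do not resolve that here.

## Chemotaxis readouts

**Cell counts** (`frame_bin_counts()`): distinct tracks per bin at each
sampled time (default every 60 s), positions linearly interpolated between
frames. Counts are standardized as Z-scores, `Z = (X − µ)/σ`
(`normalize_counts()`), and each series is then shifted so its value at
*T* = 0 is exactly zero. The Z population is one treatment within one bin,
pooled over time points and replicates — with the population rather than
sample standard deviation. Pooling per bin keeps bins comparable in the
per-bin panels; whether the original standardization pooled bins jointly
is not recoverable, so the choice is documented here and trivially
switchable. A zero-variance population yields zeros with a warning rather
than an error.

**Sine-angle orientation** (`step_sine_angle()`, `binned_mean_sine()`):
for each movement step, `(ρ_from − ρ_to) / step length`, where ρ is the
distance to the bead centre — the sine of the angle between the step and
the local tangent circle, signed positive toward the bead. It is bounded
in [−1, 1], saturates exactly for radial steps, and is antisymmetric under
reversing the step. The exact trigonometric construction behind the
published metric is not written out anywhere we could follow; this
realization satisfies the stated sign semantics and is what the package
means by "sine angle" throughout.

**Sum distance** (`sum_distance_series()`): per bin and time point, the
sum of cell-to-bead distances. Note that this is a *count-weighted*
metric: under strong attraction the bin-A sum can rise simply because
cells pour into bin A, even while each of them approaches the bead. The
total over the observation disc is the cleaner directional signal and is
emitted alongside the per-bin series.

**Windowed speed** (`binned_mean_speed()`): step speeds averaged per bin
in 30-s windows, both raw and as `log(1 + speed)` (the transform used to
normalize speed distributions). Step statistics (speed and sine angle) are
attributed to the bin of the step's spatial midpoint, so a
boundary-crossing step contributes to exactly one bin. Windows with only a
single contributing track are reported missing — one cell cannot
represent a bin mean.

**Motile fraction** (`motile_fraction()`): two matched frames a short
interval apart; a cell displaced by at most 1 µm (default) counts as
immotile. A strict "exactly the same position" rule is not robust to
localization noise, hence the 1-µm tolerance, which is recorded with the
result of every run that uses it.

**Trends** (`trend_slope()`): ordinary least squares of value against
time with the classical standard error. These are descriptive outputs.
The bin series are serially correlated (cells move slowly relative to the
60-s sampling), so the classical standard errors are anticonservative;
inference-grade analysis of such series needs correlation-aware models
(e.g. AR-1 mixed models), which are deliberately outside this package's
scope. No multiplicity correction is applied for the same reason.

## Taylor's-equation motility kinetics

The dispersal of a randomly reorienting swimmer with effective speed *v*
and decorrelation timescale *τ* follows

rms(t) = [2 v² τ (t − τ (1 − e^(−t/τ)))]^0.5,

ballistic (`v·t`) for `t ≪ τ` and diffusive (`√(4Dt)` in two dimensions)
for `t ≫ τ`. The package measures the root-mean-square *net* displacement
from each track's own first point (`rms_net_displacement()`), with linear
interpolation to the requested elapsed times; tracks shorter than a lag
drop out of that lag. Measuring from the origin (rather than averaging
all overlapping windows) reads "net distance as a function of time"
literally; the all-lag estimator is available via `method = "all_lag"`
for robustness comparisons and serves as the independent oracle in our
own validation (below).

`fit_taylor()` estimates (v, τ) by bounded Levenberg–Marquardt least
squares with a deterministic multi-start over τ ∈ {10, 1, 5, 20, 60} s.
Two defaults matter and are worth stating plainly:

* **log-spaced lags.** A 600-s series sampled every second has hundreds
  of diffusive-regime points and a handful of ballistic ones; their
  residuals are also strongly autocorrelated. Unweighted full-grid least
  squares lets the tail dominate and can drive *v* several-fold off while
  barely changing the fitted curve. The series is therefore thinned to
  ~60 approximately log-spaced lags before fitting.
* **relative weighting.** The sampling error of an RMS estimate scales
  with its value, so residuals are weighted by 1/rms². On noiseless model
  curves the fit still recovers the generating parameters to <10⁻⁴
  relative error; on simulated data it removes the tail dominance.

Both behaviours can be switched off (`thin = "none"`,
`weighting = "none"`). A fit whose τ exceeds the observed span is flagged
non-identifiable — a purely ballistic series contains no information
about τ beyond "longer than the recording".

Derived parameters (`derive_motility_params()`): decorrelation length
λ = vτ, effective diffusivity D = v²τ/n, and encounter kernel β = 4πRD
for a target of radius R. The number of dimensions defaults to n = 2,
which is the value consistent with published parameter tables for this
assay (λ²/(2τ) reproduces the printed diffusivities to their printed
precision; n = 3 would miss them by a third). β has *no default radius*:
back-solving R from published D and β gives different radii for different
conditions, so the radius that enters β must be stated explicitly, and is
echoed in all outputs. `compare_motility()` reports percent changes
between two fitted conditions.

## The track simulator

`simulate_tracks()` is the package's synthetic-data generator: an
agent-based run-and-reverse walker emulating raphid gliding. Per internal
time step (0.1 s, finer than the 1-s output sampling so that speed
statistics are not discretization-limited): the heading diffuses with
variance σ_θ²·dt; the cell advances `speed·dt`; the run terminates with
hazard λ; at a stop the heading reverses with probability q, else is
retained. Reorientation is reversal-based, not tumble-based, matching the
back-and-forth gliding of raphid diatoms; a small heading noise keeps 2-D
dispersal non-degenerate.

Chemical coupling enters in two places, both through the local steady-state
concentration of the configured gradient:

* **run-length bias** (chemotaxis): λ = λ₀·exp(−κ·u) with u ∈ [−1, 1] the
  up-gradient cosine of the heading. Positive κ lengthens bead-ward runs.
  Turning is never biased — drift arises purely from run-length
  modulation, consistent with observations of longer directional
  persistence up-gradient without directed orientation at reversals.
* **chemokinesis**: speed = s₀·(1 + g·e^(−C/C½)); a starved cell far from
  any source moves up to (1+g)-fold faster and slows toward s₀ as local
  dSi rises.

Cells reflect specularly at the arena wall and at the bead surface (they
never enter the bead disc); initial positions are area-uniform, the
stationary distribution of the unbiased walk. All draws come from a single
seeded stream, so runs are bitwise reproducible.

**Calibration of the presets** (`scenario_params()`). The unbiased
(control) preset uses s₀ = 2.3 µm s⁻¹, λ₀ = 0.114 s⁻¹, q = 0.8,
σ_θ = 0.25 rad √s⁻¹. These were chosen once so that the walker's
directional decorrelation time, 1/(2qλ₀ + σ_θ²/2) ≈ 4.7 s, and effective
diffusivity (≈12 µm² s⁻¹) match the motility measured for starved cells
around blank beads. The attractant and repellent presets set κ = ±1.5; no
quantitative behavioural rule for how dSi modulates run length has been
measured, so κ (and g) are ground-truth knobs for validating estimators,
not estimates of the real organism. The starved/replete pair uses the
chemokinesis gain to give a 2.5-fold speed ratio, mirroring the observed
more-than-twofold difference.

**The arena is closed.** The default arena radius equals the observation
radius (336 µm): the simulated chamber is the observed field. This choice
fixes the sign semantics of the scenario arms — in an open arena a
repelled population *leaves* the counted disc and the (count-weighted)
sum distance falls, indistinguishable in sign from attraction. In the
closed chamber, attraction compresses the population (total sum distance
falls) and repulsion piles cells at the outer wall (it rises).

**What the simulator does not emulate.** No hydrodynamics, no
cell–cell interactions or crowding, no adhesive-trail mechanics, no Si
uptake or depletion of the gradient (the profile is frozen at steady
state), no cell division or death, and no localization noise on
positions. Passing the package's recovery tests therefore shows that the
estimators are correct for an idealized biased run-and-reverse walker at
the recorded frame rate — not that real tracking data are free of the
segmentation and linking artefacts that upstream tools must handle.

## Validation strategy and problem sizes

The test suite validates each formula against hand-computed values and
each estimator against the simulator's known ground truth: noiseless
Taylor curves must be recovered to 10⁻⁴ relative; on 100 unbiased
simulated cells recorded for 600 s at 1 fps, the fitted *v* must land
within 10% of the walker's gliding speed and the fitted *D* within 15% of
an independent all-lag MSD regression over the diffusive regime
(lags 60–150 s); a 20-seed null suite checks isotropy (grand mean sine
angle within 3 SE of zero) and documents the serial-correlation
miscalibration of classical OLS trend errors discussed above; single
attractant and repellent runs must show their defining directional
signatures. These sizes (100–150 cells, 600 s, 20 seeds) are the
package's standard validation conditions and match the recordings the
assay produces.

```{r example, eval = FALSE}
report <- run_experiment(list(scenario = "attractant", seed = 1))
report$comparison
```

## Known limitations

* Classical OLS trend errors on bin series are anticonservative under
  serial correlation; treat `trend_slope()` p-values as descriptive.
* Sum distance is count-weighted; interpret per-bin slopes together with
  the count series, or use the total.
* Mean 1-s chord speeds underestimate the instantaneous gliding speed by
  a few percent whenever the heading decorrelates within a frame; the
  Taylor *v* estimates the instantaneous speed.
* The flat-chamber gradient form is an empirical calibration, not a
  derivation; concentrations very close to the bead surface are outside
  both variants' reliable range.
* The XML reader consumes only the spot/edge subset of the tracking
  export dialect; exotic exports should go through the CSV route.
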