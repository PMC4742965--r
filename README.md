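# beadtaxis

Quantification of diatom chemotaxis in bead-based nutrient-gradient
assays.

Benthic pennate diatoms glide over sediments in search of dissolved
silicic acid (dSi), the building block of their cell wall. A standard way
to test whether starved cells can *find* a local dSi hotspot is the bead
assay: a micrometre-scale aluminium-oxide particle loaded with silicate
is placed in a shallow chamber, a diffusion gradient forms around it, and
cells are filmed for 600 s at 1 frame per second. `beadtaxis` implements
the full quantitative analysis of such recordings, for microbial
ecologists and biophysicists working with gliding-cell tracking data:

* **Gradient model** — the bead as a constant point source: per-particle
  loading, steady-state profile `C(r) = i/(4π√r D)` (flat-chamber form;
  the spherical `i/(4πDr)` is available as an alternative), equilibration
  time `d²/D`, and released fraction `min(1, i·t/L)`.
* **Bin geometry** — three concentric 112-µm annuli (bins A–C) around the
  bead; 0.355 mm² counting area.
* **Chemotaxis metrics per bin** — cell counts with baseline-anchored
  Z-score normalization `Z = (X−µ)/σ`; sine-angle orientation
  `(ρ_from − ρ_to)/step length` (positive toward the bead); sum of
  cell-to-bead distances; 30-s windowed mean speed (raw and log(1+s));
  motile fraction from two-frame overlays; OLS trend slopes.
* **Motility kinetics** — root-mean-square net displacement fitted to
  Taylor's equation, rms(t) = [2v²τ(t − τ(1 − e^(−t/τ)))]^0.5, with
  derived decorrelation length λ = vτ, effective diffusivity D = v²τ/n
  (n = 2 dimensions) and encounter kernel β = 4πRD, plus per-condition
  comparisons.
* **Track simulator** — an agent-based run-and-reverse walker with
  gradient-biased run lengths (chemotaxis) and concentration-coupled
  speed (chemokinesis), used to validate every estimator against known
  ground truth.
* **I/O** — CSV track tables, a subset of the TrackMate XML export, and
  YAML/JSON assay-geometry configs.

## Worked example

Simulate a control arm (blank bead) and an attractant arm (dSi-loaded
bead) under the standard assay conditions, compute every metric and
compare the fitted motility parameters:

```r
library(beadtaxis)
report <- run_experiment(list(scenario = "attractant", seed = 1))
report
```

```
experiment_report — scenario: attractant | seed: 1
  observation area: 0.355 mm^2; gradient: literal profile
  control   N = 100  v = 2.43 um/s  tau = 3.30 s  D = 9.73 um^2/s
  treatment N = 100  v = 2.03 um/s  tau = 14.77 s  D = 30.43 um^2/s
  percent change (treatment vs control):
 parameter           a            b percent_change
         v    2.427617     2.030055      -16.37662
       tau    3.300658    14.767174      347.40089
    lambda    8.012733    29.978179      274.13174
         D    9.725924    30.428680      212.86160
      beta 6110.977972 19118.903527      212.86160
```

Reading this: both arms glide at ~2 µm/s, but cells in the gradient keep
their direction ~4× longer (τ: 3.3 → 14.8 s), so their decorrelation
length λ, dispersal coefficient D and encounter kernel β all rise — the
signature of chemotaxis through run-length modulation rather than faster
swimming. The treatment arm's sum-distance trends are negative
(`report$arms$treatment$sum_distance_trends`), i.e. the population
contracts toward the bead, while the control trends sit within two
standard errors of zero.

The gradient itself:

```r
g <- point_source_gradient()           # i = 1.21e-13 mol/s, D = 1e-5 cm^2/s
steady_state_concentration(g, r_um = 336)$conc_uM  # 5.25 uM at the field edge
time_to_steady_state(g, d_um = 672)                # 451.6 s to steady state
fraction_released(g, 600)                          # 0.052 of a 1.4-nmol load
```

A command-line wrapper over the same functions lives at
`inst/scripts/beadtaxis-cli.R` (subcommands `simulate`, `gradient`,
`analyze`, `report`).

## Package layout

* `R/` — implementation (tracks & geometry, gradient model, simulator,
  Taylor kinetics, chemotaxis metrics, pipeline).
* `tests/testthat/` — unit, property and end-to-end scientific tests.
* `vignettes/bead-assay-methods.Rmd` — the models, their assumptions,
  parameter choices and known limitations, in detail.
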