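Package: beadtaxis
Title: Quantification of Diatom Chemotaxis in Bead-Based Nutrient Gradient Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chemotaxis of gliding benthic diatoms toward
    micro-bead point sources of dissolved silicic acid. Implements the
    steady-state point-source diffusion model of a nutrient-loaded bead
    (loading, flux, concentration profile, time to steady state, released
    fraction), per-bin chemotaxis readouts around the bead (normalized cell
    counts, sine-angle orientation, sum distance, windowed speed, motile
    fraction), Taylor's-equation fitting of root-mean-square net displacement
    with derived motility parameters (decorrelation length, effective
    diffusivity, encounter kernel), and an agent-based run-and-reverse track
    simulator with gradient-biased run lengths and chemokinetic speed coupling
    for generating trajectories with known ground truth. Readers are provided
    for tabular track exports and a subset of the TrackMate XML format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xml2,
    jsonlite,
    yaml,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
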