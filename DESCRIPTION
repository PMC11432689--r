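Package: seroraft
Title: Serotonin-Membrane Interaction Analysis for Bilayer Trajectories
    and Langmuir Monolayer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how an amphipathic neurotransmitter such as
    serotonin engages model lipid membranes. Provides membrane-contact
    scoring, species-wise protrusion profiles and insertion-onset
    detection for multi-frame trajectories; pi-stacking dimer detection
    with dissociation events and geometric contact classification
    (hydrogen bond, CH-pi, van der Waals); critical micelle concentration
    estimation by continuous two-segment break-point regression of
    surface-tension curves; Langmuir monolayer adsorption-kinetics
    fitting with one-way ANOVA and Tukey HSD group comparison; and
    grayscale aggregate-area quantification of tensiometer drop
    snapshots. A seeded synthetic-data module generates membrane
    trajectories, tensiometry and kinetics curves and aggregate image
    series with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mgcv,
    minpack.lm,
    png,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
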