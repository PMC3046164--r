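Package: numotion
Title: Second-Order Motion Numerosity Stimuli, Occupancy Models, and
    Scalar-Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates visual numerosity displays in which a variable number
    of bars moves over a random-texel background either as luminance-defined
    (first-order) items or as contrast-defined (second-order) items whose
    polarity-inverting texture carries no luminance signature in any single
    frame.  Implements the occupancy family of perceptual numerosity models
    (fixed-radius union-of-disks occupancy, the density-adaptive normalized
    variant, and the equivalent luminance spatial-filtering route), a
    simulated observer producing power-law numerosity estimates with
    constant-coefficient-of-variation multiplicative noise, and the analysis
    chain for such estimate tables: scalar-variability diagnostics,
    per-subject multiple regression on log numerosity and log bar height,
    two-factor repeated-measures ANOVA, and cross-condition agreement.
    Includes a trial-schedule builder (calibration, practice, experiment
    proper) and frame/layout export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
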