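Package: glossprobe
Title: Modelling Specular Highlight Perception on Glossy Textured Surfaces
Version: 0.1.0
Authors@R:
    person("Gloss", "Probe Developers", email = "glossprobe@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how specular highlights are distinguished from
    bright texture markings on glossy, undulating surfaces. Provides a
    procedural stimulus generator with exact per-pixel ground-truth specular
    maps, a global-intensity threshold baseline, probe-pixel selection by
    agreement between ground truth and the threshold baseline, a multi-scale
    tiered convolutional network trained to recover the specular component, a
    genetic-algorithm pruning stage that fits the trained network to sparse
    per-pixel binary judgments, simulated observers with idiosyncratic
    response behaviour, and downstream analyses: decision-rate curves,
    rotated-highlight tests, representational similarity analysis and
    single-unit lesioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
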