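Package: attnwarp
Title: Attentional Warping of Color Perception: Design, Simulation and
    Signal-Detection Analysis
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how feature-based attention biases the
    perceived color of a visual-search target away from distractor colors.
    Provides deterministic trial-design generators for a family of oddball
    search + two-alternative forced choice (2AFC) similarity-judgment
    experiments on a 360-degree CIELab color wheel, a generative
    signal-detection observer with a repulsive bias of the internal target
    representation, d-prime summaries and maximum-likelihood fitting of the
    bias model, chance-point bias inference, and a simulation of a
    color-tuned neural population under feature-similarity attentional gain
    whose representational geometry is examined with classical
    multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
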