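Package: holokin
Title: Geometric Ensemble Analysis of CaMKII Holoenzyme Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-particle geometric ensemble analysis for ring-shaped
    multimeric holoenzymes such as CaMKII alpha and beta. Provides a
    synthetic holoenzyme coordinate generator with ground-truth state
    labels (extended, dimerized, compact subunits; 12/14/16-mer hub
    stoichiometries; inter-holoenzyme clustering; pixel-scale noise),
    the negative-stain EM measurement conventions (kinase radius with
    appended domain radius, linker extension, nearest-clockwise neighbor
    separation), distance-threshold state classifiers, an angular-Fourier
    hub symmetry census, ensemble distribution statistics with
    Gaussian-chain polymer null models and Monte-Carlo deviation tests,
    and cooperative-activation analysis (variable-slope Hill fits with
    extra-sum-of-squares F comparison, Michaelis-Menten fractional
    velocities, stochastic trans-autophosphorylation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
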