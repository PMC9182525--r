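Package: enameldev
Title: Multimodal Characterization of Developing Dental Enamel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the physical maturation of dental enamel from
    multimodal measurements taken over the first weeks of postnatal life.
    Extracts crystallite size and hexagonal lattice constants from X-ray
    diffractograms (Scherrer analysis with apparatus-broadening correction),
    carbonate-to-phosphate ratios and crystallinity indices from ATR-FTIR and
    Raman spectra, surface roughness and DMT elastic-modulus distributions
    from AFM height and stiffness maps, and Ca/P composition ratios from EDS
    tables. The thirteen extracted structural features feed a standardized
    multilayer-perceptron regressor that predicts the day of postnatal life,
    with growth-method architecture search and sensitivity-based feature
    pruning. A deterministic synthetic-data generator, parameterized by
    per-feature age trajectories, emulates every input modality so the whole
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
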