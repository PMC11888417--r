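Package: coneorg
Title: Quantitative Modeling of Optoretinographic Cone Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models and quantifies light-evoked optical path length (OPL)
    changes of human cone photoreceptor outer segments measured with
    phase-sensitive optical coherence tomography (optoretinography, ORG).
    Provides a four-parameter biexponential response model and its variants
    for paired flashes, pulse trains and adapting backgrounds; constrained,
    contraction-weighted nonlinear least-squares fitting with 95 percent
    confidence bounds; stimulus radiometry (photon flux and photopigment
    bleach fraction) and dose-response characterization; extraction of
    per-cone OPL traces from complex ISOS/COST OCT samples via vector-sum
    phase differences with temporal unwrapping; observation-window
    sensitivity analysis; and synthetic-data generators for parameter
    recovery and Monte Carlo studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
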