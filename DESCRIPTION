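Package: textprior
Title: Hybrid Screening with Text-Score Priors for Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage psychiatric screening designs that combine a
    keyword-based text classifier of trauma self-narratives with a
    two-parameter logistic (2PL) item response model of a dichotomous symptom
    questionnaire. A product-score text classifier turns each narrative into a
    standardized score; a Bayesian latent regression converts that score into
    an informative normal prior for the latent trait, which is then estimated
    by expected a posteriori (EAP) quadrature or by Markov chain Monte Carlo.
    Includes information-based adaptive item routing, standard-setting methods
    for locating a diagnostic cutoff on the latent scale, screening
    performance metrics, and seeded synthetic-cohort generators for
    simulation studies. Ships the 21-item NCS-R PTSD item parameter bank.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
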