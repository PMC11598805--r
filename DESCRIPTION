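Package: retnet
Title: Double-Loop Neural Network Estimation of Metal Retention in the Body
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates retention of heavy metals (zinc, chromium, copper,
    lead) in the human body from environmental exposure and physiology.
    Implements the renal clearance statistic (Reberg clearance with a
    Mosteller-style body-surface correction and an exponential retention
    transform), from-scratch multilayer perceptron blocks trained with
    resilient backpropagation (RPROP), and an error-weighted closed-loop
    fusion of a long-term and a short-term exposure block.  Includes a
    seeded synthetic-cohort generator with planted ground truth so the
    whole pipeline can be trained and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
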