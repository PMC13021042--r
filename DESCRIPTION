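Package: simbias
Title: Observer Models and Analyses for Similarity-Induced Working-Memory Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how perceptual comparisons distort visual
    working-memory reports on circular stimulus spaces. Implements von Mises
    observer models that either integrate a memory representation with a
    subjectively similar probe (normalized-product joint density) or
    occasionally swap the probe for the memory item (mixture density),
    together with a seeded generator of continuous-report experiments
    (single-probe similarity judgments, 2AFC probe pairs, and an
    individual-differences design), the signed-offset and ambivalent-probe
    analysis pipeline, von Mises precision estimation, model fitting with
    AIC/BIC comparison, parameter- and model-recovery studies, and
    noncentral-t / Fisher-z power utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
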