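Package: concordia
Title: Cross-Disease Transcriptome Concordance and Cytokine Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying directional overlap between the
    differential-expression signatures of two case/control cohorts
    (for example lesional psoriatic skin and advanced atherosclerotic
    plaque), attributing a shared gene signature to upstream cytokine
    drivers with a stimulation-signature compendium and signed
    hypergeometric enrichment statistics, correlating disease and
    stimulation fold-change profiles by Spearman rank correlation, and
    scoring two-cytokine synergy from qPCR Ct tables via delta-delta-Ct
    quantification and a Bliss-style multiplicative null model. Includes
    a synthetic-data generator with planted ground truth so the full
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
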