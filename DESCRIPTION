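Package: drugsig
Title: Proteome-Wide Interaction Signatures for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds compound-proteome interaction signatures from binding-site
    prediction tables (template-ligand fingerprint similarity weighted by site
    confidence), ranks compounds by signature or ligand-fingerprint similarity,
    and benchmarks drug-repurposing pipelines by leave-one-out recovery of
    known drug-indication associations. Implements indication accuracy and its
    consensus-list analogue, normalized discounted cumulative gain, closed-form
    hypergeometric and Monte-Carlo random controls, a per-list uniqueness
    filter that suppresses near-duplicate analog pairs, rank- and score-based
    data fusion, consensus candidate prediction with binomial tail
    probabilities, and gold-standard target-overlap analyses. A synthetic-study
    generator with planted indication structure makes every stage testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
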