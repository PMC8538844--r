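Package: tmmpipe
Title: Telomere Maintenance Mechanism Classification and Survival Analysis
    from Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Pan-Cancer", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-sample gene-set enrichment scoring of telomerase and
    alternative-lengthening-of-telomeres (ALT) signatures, four-way telomere
    maintenance mechanism (TMM) classification of tumor samples (TEL, ALT,
    TEL+ALT, NDTMM), Kaplan-Meier and log-rank survival stratification,
    empirical-Bayes moderated-t differential expression, hypergeometric
    over-representation, and mutation / copy-number burden profiling.
    Includes a synthetic multi-cohort data generator with planted TMM
    structure so the whole pipeline is testable without external downloads,
    plus a configuration-driven end-to-end runner and command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    optparse
Config/testthat/edition: 3
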