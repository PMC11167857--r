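Package: histodiff
Title: Histone PTM Site-Occupancy Quantification and Covariate-Conditioned
    Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the site occupancy (relative abundance, beta-value,
    M-value) of histone post-translational modifications from peptide-level
    normalized-area tables produced by bottom-up proteomics with three
    parallel digests, tests occupancy differences between treatment groups
    with Welch t-tests on M-values, corrects for multiple testing with a
    covariate-conditioned false discovery rate regression (conditioned
    q-values), classifies modifications for volcano display, maps
    modification sites onto homologous proteins of other species by global
    pairwise alignment, and ships a seeded synthetic-data generator with
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
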