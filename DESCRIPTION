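Package: ppiface
Title: Variability of Protein-Protein Interfaces Across Biological Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates protein-protein interfaces in biological assemblies
    using a combined distance and buried-surface-area (dASA) contact
    definition, quantifies pairwise interface similarity (Face Position
    Similarity, CAPRI-style L_rms and I_rms), organises hetero-dimers into a
    three-level redundancy hierarchy (identical sequence pair, identical
    protein pair, identical family pair) and estimates redundancy-corrected
    interface similarity distributions with and without best-match filtering
    of homo-oligomer induced diversity. Includes a generator of synthetic
    biological assemblies with known binding-mode structure so that every
    stage of the analysis can be validated against analytic expectations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
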