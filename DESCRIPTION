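Package: serotarget
Title: Seromics-Guided Tumor Antigen Discovery and Neo-Epitope Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multi-omics pipeline for prioritizing tumor antigens
    in high-grade serous ovarian carcinoma (HGSC) and related cancers.
    Implements Z-Factor hit calling on protein-array auto-antibody signals,
    cross-patient repertoire set algebra with a differential-signal test,
    expressed somatic variant filtering from paired WES and RNA-seq calls,
    mutation-centered neo-epitope peptide tiling with a pluggable MHC
    affinity/processing predictor contract, integration of target genesets with
    tumor and thymic mTEC expression tables, eluted MHC-associated peptide
    (MAP) to proteome matching with geneset annotation and screening-panel
    assembly, and a fully synthetic multi-patient cohort generator with a
    ground-truth ledger so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
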