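Package: ervatlas
Title: Detection, Dating and Expression Analysis of Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for genome-wide characterization of
    LTR-retroelement (endogenous retrovirus, ERV) insertions, built around a
    zebrafish-style survey. Provides a synthetic-genome simulator that plants
    proviruses of known age, structure, class and protein-motif content plus
    matched expression matrices; a simplified k-mer-seeded LTR-pair detector
    with composite evidence scoring; structural classification and a
    reversible locus-based nomenclature; molecular dating from 5'/3' LTR
    divergence (T = D/(2R)); per-chromosome density and chi-square enrichment
    statistics; Gag/Env protein feature annotation (ORFs, furin site,
    immunosuppressive domain, cysteine motifs, transmembrane segments); and
    TPM/FPKM-based expression filtering with specificity, virus-response and
    cis/trans association calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
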