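Package: beetMBS
Title: Mapping-by-Sequencing of Beet Cyst Nematode Tolerance
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for localizing a quantitative nematode-tolerance locus in
    sugar beet by bulked-segregant mapping-by-sequencing. Implements cyst-count
    phenotype transformation and incomplete-block adjustment, extreme-pool
    selection, parent/F1-contrast variant filtering, a pooled delta
    allele-frequency windowed genome scan with run-based interval
    delimitation, and KASP-style marker candidate design, together with a
    seeded synthetic F2 pool-seq generator so the whole analysis runs at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
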