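Package: varfunnel
Title: Pedigree-Based Prioritization of Rare Germline Variants in Cancer Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable engine for prioritizing rare germline variants in
    high-risk cancer families from multi-sample annotated variant tables or
    VCF files plus a pedigree. Implements a staged funnel: site/sample
    quality filtering, population-frequency filtering, pedigree segregation,
    CADD-tier ranking, a 12-tool missense deleteriousness consensus, gene
    intolerance (RVIS/pLI/missense-Z) and conservation (GERP/phastCons/phyloP)
    gates, Grantham substitution scoring, and regulatory routing of
    non-coding variants against enhancer/promoter/super-enhancer/UCNE/
    ultrasensitive region sets. Emits ranked candidates with a stage-by-stage
    funnel report, and ships a synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
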