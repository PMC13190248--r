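Package: duplexsoma
Title: Somatic Evolution in Normal Tissue from Deep Duplex Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutations called from high-depth
    duplex sequencing of histologically normal tissue. Provides post-consensus
    variant filtering (quality rules, Kolmogorov-Smirnov read-position artefact
    removal, germline SNP identification, cohort-level binomial contamination
    filtering, blood-like classification), B-allele-frequency based detection of
    clonal copy-number change and tumour contamination, mutational-signature
    exposure refitting with per-mutation attribution, per-cell mutation burden
    and dose-response estimation for smoking, alcohol and platinum exposure,
    and coverage-adjusted dN/dS selection inference on a targeted panel. A
    synthetic cohort generator with full truth records makes the entire
    pipeline testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
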