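Package: crisprAudit
Title: Population-Aware Off-Target Auditing for CRISPR/Cas9 Guides
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end audit of candidate off-target sites for a single
    SpCas9 single-guide RNA. Provides bulge-aware banded alignment of
    candidate sequences against the guide, SEED and PAM conservation checks,
    CFD (cutting frequency determination) mismatch scoring with an indel
    extension and a multiplicative final cleavage-probability score,
    merging and filtering of off-target predictor outputs, genic and
    repeat annotation, overlay of population variants with per-population
    allele frequencies (polymorphic-site calling, mismatch/indel effect
    classification, PAM disruption and creation), population privacy
    summaries, a deterministic synthetic-data generator with planted
    truth, and a command-line audit driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
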