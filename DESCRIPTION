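Package: breaktracer
Title: Tumor-Informed ctDNA Minimal Residual Disease Tracking with
    Breakpoint-Spanning ddPCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Workflow for tumor-informed monitoring of circulating tumor
    DNA (ctDNA) in translocation-driven cancers such as Ewing sarcoma.
    Parses structural-variant breakends (VCF BND records or bracketed
    breakpoint notation), builds the patient-specific junction reference
    from a genome FASTA, designs breakpoint-spanning droplet digital PCR
    (ddPCR) assays with a junction-overlapping hydrolysis probe, checks
    specificity by in-silico PCR, quantifies droplet data into copies per
    millilitre plasma and allelic fraction by Poisson statistics, and
    calls longitudinal minimal residual disease (MRD) status transitions
    (molecular response, recurrence, rising/falling trends). Includes a
    fully seeded synthetic-data generator (toy genomes with implanted
    translocations, droplet wells, whole patient courses) with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
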