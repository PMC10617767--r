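Package: ampliconlens
Title: Architecture of Cancer Gene Amplicons from Rearrangements and Copy Number
Version: 0.1.0
Authors@R:
    person("Amplicon", "Lens Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of the genomic architecture of the 8p11-p12 amplicon in
    squamous cell lung cancer. Classifies structural rearrangement junctions by
    breakend orientation (tail-to-tail, head-to-head, deletion- and
    duplication-type), detects fold-back inversions, applies gene-window rules
    for intragenic and near-gene tail-to-tail events at FGFR1, predicts
    ectodomain-deficient FGFR1 open reading frames from intragenic
    rearrangements, calls NSD3 SET-domain disruption, summarises segmented copy
    number with the ROBOCOP rolling-binmeans profile, simulates and infers
    breakage-fusion-bridge (BFB) amplification via palindromic count-vector
    search under a Poisson model, and performs cohort-level Fisher association
    of rearrangement status with FGFR-inhibitor sensitivity. Ships a seeded
    synthetic-cohort generator so the whole pipeline is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
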