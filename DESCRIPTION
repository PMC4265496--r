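Package: hmrnuc
Title: Nucleosome Organization at Hypomethylated Region Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of nucleosome organization at the boundaries of
    hypomethylated regions (HMRs). Builds smoothed per-base nucleosome
    occupancy tracks from paired-end MNase-seq fragments, calls HMRs from
    per-CpG methylation counts with a two-state beta-binomial hidden Markov
    model, scores intrinsic nucleosome occupancy (INOS) with a 147-bp
    sliding-window k-mer Lasso model, and quantifies boundary-anchored
    occupancy metaprofiles, phasing periodicity, cross-tissue HMR classes,
    6-mer and E-box enrichment at boundary CGs, and ROC/AUC comparison of
    sequence-based nucleosome predictors. Includes a fully seeded synthetic
    data generator (genome, methylomes, fragments, planted motifs) with
    complete ground truth, so every stage of the pipeline is testable
    end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
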