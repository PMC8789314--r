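Package: tribepas
Title: RNA-Editing Based Target Calling and Poly(A)-Site Analysis for
    HyperTRIBE Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify RNA-binding-protein target transcripts from
    HyperTRIBE experiments (ADAR-fusion A-to-G editing) and to analyse
    polyadenylation from oligo-dT-primed (Smart-seq2) libraries. Implements
    strand-aware base-count pileups, a replicate-aware beta-binomial test of
    differential editing proportions with optional expression covariates,
    SNP and A-to-G filtering, untemplated poly(A)-tail detection and
    trimming, an oligo-dT internal-priming filter, subtractive
    kernel-density poly(A)-site-cluster (PAC) calling with replicate
    consensus, dominant-PAC/PAS shift statistics between genotypes, and set
    algebra over target gene lists. A synthetic-data module generates toy
    genomes and ground-truth-labelled experiments so the whole pipeline can
    be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
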