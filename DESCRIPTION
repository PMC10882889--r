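Package: lncscreen
Title: Discovery and Functional Characterization of Stress-Responsive lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate long non-coding RNAs
    (lncRNAs) from assembled transcriptomes and characterizing their function.
    Covers the discovery cascade (reference-overlap exclusion, structural
    filters on transcript length and intron size, isoform merging, a
    transparent rule-based coding-potential classifier), differential
    expression filtering with sign-consistent intersection across comparisons,
    tumor-versus-normal cohort statistics with a random-gene-set correlation
    null, peptide-sensor kinase-activity profiling with ATP-standard
    calibration and uncentered-correlation clustering, and closed-form
    pharmacology analytics (Bliss-model combination index, comparative-Ct
    relative expression, nuclear-cytoplasmic enrichment, tumor volume).
    A synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
Config/testthat/edition: 3
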