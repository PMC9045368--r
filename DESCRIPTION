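Package: sigmacall
Title: Bacterial TSS Calling, Promoter Motif Discovery and RpoD Consensus Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls transcription start sites (TSSs) from per-position 5'-end
    read counts of enriched (Cappable-seq style) primary-transcriptome
    libraries, extracts strand-aware promoter windows (-90..+10) from replicon
    sequences, discovers -35/-10 promoter motifs with a constrained
    two-motif-set hidden Markov model trained by Viterbi training with random
    restarts, and scores each promoter against the sigma-70 (RpoD) consensus
    (TTGACA/TATAAT) with positional and spacer penalties to classify TSSs
    into RpoD-dependence probability tiers. Includes a synthetic-data
    generator that plants promoters into simulated replicons so every stage
    of the pipeline can be benchmarked against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
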