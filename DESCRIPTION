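Package: squigalign
Title: Basecaller-Guided Nanopore Signal Alignment and Pore Model Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns raw nanopore current traces ("squiggles") to nucleotide
    references with basecaller-guided banded dynamic time warping, stores the
    resulting signal alignments as compact per-reference-position statistics
    in BAM auxiliary tags, trains k-mer pore models de novo from basecaller
    move metadata, and computes alignment-comparison and modification-detection
    statistics (two-sample Kolmogorov-Smirnov and z-scores). Includes a
    squiggle simulator with full ground truth so the whole pipeline can be
    exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Rsamtools,
    Biostrings,
    e1071,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
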