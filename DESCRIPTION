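Package: spliceGC
Title: GC Content, Pre-mRNA Secondary Structure, and Splice-Site Usage
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how GC content around exon-intron junctions
    relates to splice-site usage through the stability of local pre-mRNA
    secondary structure. Classifies splice sites from transcript models
    (alternative, constitutive, skipped, first-exon), extracts fixed-width
    sense-strand junction windows and their GC metrics, predicts minimum
    free energy with a simplified temperature-aware nearest-neighbor
    folding model (with an exhaustive-enumeration oracle), selects decoy
    splice sites as matched controls via a position log-odds scorer,
    generates mononucleotide and dinucleotide-preserving (Euler path)
    shuffle nulls, and runs the rank-test / regression / GC-matched-bin
    statistical battery end-to-end on synthetic genomes with planted
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
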