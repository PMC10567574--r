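Package: pirnapipe
Title: Classification and Quantification of C. elegans piRNAs and Their Precursors
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A small-RNA sequencing analysis toolkit for Caenorhabditis elegans
    piRNAs (21U RNAs). Implements NEXTflex-style adapter trimming with
    randomized-base removal and size selection, a one-mismatch best-hit short
    read aligner for small genomes, strand-aware classification of aligned
    reads into structural, mature piRNA, piRNA precursor and other classes,
    per-locus counting with reads-per-million normalization against
    structural-RNA-filtered totals, normalized coverage tracks and
    mutant-versus-wild-type comparison tables. Also provides an executable rule
    model of the substrate specificity of the PUCH endonuclease (cap chemistry,
    position-3 uridine, subunit and divalent-cation requirements) and a
    synthetic-data generator producing genomes, annotations and genotype-aware
    read sets with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
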