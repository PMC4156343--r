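Package: refguide
Title: Reference-Guided Low-Coverage Genome Assembly and Genome-Content
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided draft genome assembly for low-coverage
    (roughly 3-6x) short-read resequencing of species without their own
    assembled genome, together with the genome-content statistics used to
    assess such drafts. Maps paired-end reads to a related species' genome
    with a seed-and-extend aligner under unit edit costs, extracts a
    reference-anchored consensus at configurable minimum-coverage
    thresholds (ambiguous positions as N, polymorphic positions as IUPAC
    codes), splits the consensus at long poly-N runs, and computes
    contiguity statistics (N50, length histograms, fold coverage), perfect
    microsatellite (SSR) densities, windowed GC-content heterogeneity
    against the homogeneous-genome null, and a two-stage filtered
    heterozygous-variant spectrum with a transition/transversion summary.
    A synthetic-data module simulates diverged diploid genomes with
    planted features and quality-decay paired-end reads so that every
    stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
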