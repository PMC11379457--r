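Package: cais
Title: Codon Adaptation Index of Species and GC-Corrected Codon Usage Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Species-level codon adaptation metrics that separate the
    signature of selection on synonymous codon usage from nucleotide
    composition and amino acid composition. Implements the Codon Adaptation
    Index of Species (CAIS), a Kullback-Leibler divergence of observed codon
    usage from the usage expected under the genome's GC content, standardized
    to a reference amino acid composition; the classic Codon Adaptation Index
    (CAI) from relative synonymous codon usage; and a GC-corrected Effective
    Number of Codons (ENC) that treats the stop codons as a three-codon
    family. Includes local-GC variants built from merged coding-sequence
    catchment regions of a genome annotation, a stationary
    mutation-selection-drift genome simulator for validation, Brownian trait
    simulation on phylogenies, and comparative statistics (phylogenetic
    independent contrasts, mixed-model species effects).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    lme4,
    stats,
    utils,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
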