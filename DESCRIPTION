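Package: ChromAnchor
Title: Synteny- and Genetic-Map-Guided Pseudochromosome Construction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds chromosome-scale pseudomolecules from de novo contigs by
    combining two anchor maps: a gene-synteny map derived from best hits of
    reference gene models against the contigs, and a genetic-marker map from
    SNP flank alignments with centimorgan positions. Detects and splits
    chimeric contigs from conflicting anchor runs, orders and orients contigs
    by a deterministic weighted rank consensus, and emits pseudomolecule
    FASTA, AGP 2.1 and placement statistics. Companion analyses classify
    structural variants between haplotype alignments (Assemblytics-style sign
    table), detect collinear gene chains in rank space with per-pair
    synonymous substitution rates (Nei-Gojobori 1986), and scan fixed genomic
    windows for functional-category enrichment (Fisher's exact test with
    Holm correction). A seeded simulator generates synthetic genomes with
    known contig order, orientation and chimera truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GenomeAssembly, Alignment, Genetics, SNP, Software
RoxygenNote: 7.3.3
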