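Package: matlocus
Title: Mating-Type Locus Mining, Telomere Scanning and Tetrapolar
    Compatibility for Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the mating system of tetrapolar
    basidiomycete monokaryons from genome assemblies and annotations.
    Locates the A mating-type locus as a divergently transcribed
    homeodomain (HD1/HD2) gene pair, locates the B (pheromone/receptor)
    locus by scanning the flanks of STE3 pheromone-receptor genes for
    open reading frames and filtering translated peptides on a CaaX
    prenylation motif plus conserved N-terminal AF/ER signatures, types
    alleles by global protein identity, infers pairwise sexual
    compatibility under the tetrapolar rule, detects telomeric repeat
    monomer arrays at chromosome termini, compares locus-scale gene
    microsynteny between strains, and calls strain-specific genes by a
    zero-reciprocal-match rule. A seeded synthetic-genome generator
    emits multi-strain FASTA/GFF3/protein files with planted loci,
    telomeres and allele divergence, together with a machine-readable
    truth manifest, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
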