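Package: tgmap
Title: Transgene Integration-Site Mapping from Shallow Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps the genomic integration site of a multi-copy transgene
    from shallow (around 8X) paired-end whole-genome sequencing.
    Implements the full inference chain as reusable, tested functions:
    classification of discordant read pairs and soft-clipped (split)
    reads from SAM alignments, single-linkage clustering of
    inter-chromosomal pairs into candidate rearrangement links,
    read-depth duplication scoring over the transgene-homologous donor
    loci, rule-based filtering and ranking of candidates, split-read
    breakpoint resolution with junction microhomology and deletion
    detection, coverage-ratio cassette copy-fold estimation, and design
    plus in-silico validation of a three-primer zygosity genotyping PCR.
    A synthetic-locus simulator generates ground-truth transgenic and
    wild-type alleles, paired-end reads, and oracle local-mode
    alignments so the entire pipeline runs and is testable without any
    external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
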