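Package: mitohet
Title: Mitochondrial Off-Target Variant Calling and Heteroplasmy Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genotyping the mitochondrial genome from short-read
    alignments recovered as off-target material of exome capture. Parses SAM
    alignments against a circular mtDNA reference, marks PCR duplicates,
    builds per-position pileups, and calls mismatches, insertions and
    deletions under quality-score, read-depth and flanking-region filters.
    Every call carries its heteroplasmic fraction (variant read depth over
    total read depth at the site, or at the 5' anchor for insertions).
    Downstream, the package builds IUPAC-coded consensus genomes, assigns
    haplogroups from a user-supplied definitions table with a reliability
    score, and provides cohort analytics: locus and homopolymer annotation,
    pathogenicity aggregation, heteroplasmic-fraction class matrices,
    hierarchical clustering and group comparison statistics. A
    heteroplasmy-aware paired-end read simulator with truth tables makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
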