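Package: refcurate
Title: Reference-Guided Curation of Draft Genome Assemblies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a fragmented draft assembly into a curated,
    chromosome-scale reference with the help of a finished donor genome:
    contig-to-chromosome tiling with coverage-confirmed mis-assembly
    splitting, two-step donor gap filling with lowercase provenance,
    haploid-aware small-variant benchmarking (modified false-positive
    accounting and Phred-scaled QV), benchmark-driven base correction, a
    flank-anchored structural-variant presence assay, population
    major-allele harmonization with allele-frequency-binned accounting, and
    annotation-transfer quality control including protein-consequence
    classification. A deterministic synthetic diploid genome generator with
    full truth sets makes every stage testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    yaml
Config/testthat/edition: 3
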