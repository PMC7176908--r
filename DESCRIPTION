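Package: introscan
Title: Introgression Mapping of Binary Traits in Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping a qualitative trait locus carried on a donor
    introgression in a backcross population genotyped with a biallelic SNP
    array. Provides marker triage against the two parents (monomorphic,
    single-parent, unmapped and parent-heterozygous exclusion classes),
    graphical-genotype encoding of progeny calls, detection of contiguous
    donor-carrying segments, delimitation of the minimal candidate region
    whose donor state co-segregates perfectly with a binary phenotype,
    candidate-gene lookup against a GFF3/BED annotation, and transformation
    assay summaries. A meiosis-level simulator of marker-assisted backcross
    programs generates populations with the full category structure of a
    real array panel, so every stage of the pipeline can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
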