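Package: goldscan
Title: Split-Read Genotyping and Mixed-Model Association for an Intronic
    Inverted-Repeat Insertion Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a Mendelian-dominant colour polymorphism to a
    transposon-derived insertion: simulation of diploid cohorts and
    breakpoint-realistic short-read alignments, split-read (soft-clip)
    genotyping of a structural variant at a known breakpoint, linear
    mixed-model association with a centered kinship matrix and
    likelihood-ratio tests, haplotype-comparison insertion discovery,
    inverted-repeat (DNA cruciform) characterization, and
    genotype-phenotype concordance accounting with incomplete penetrance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
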