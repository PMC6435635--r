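Package: bacpopscan
Title: Population Variant Scanning and Consensus Genome Comparison for
    Clonal Bacterial Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterising the population genomics of a clonal
    bacterial culture from per-site read pileups: multi-sensitivity
    minor-allele-frequency scans for sub-consensus variants, hypermutation
    hotspot detection with within-gene positional statistics, collinear
    whole-genome comparison of a strain consensus against a reference
    (SNPs, small deletion-insertion polymorphisms, and multi-kilobase
    deleted segments such as prophage-like regions), codon-level variant
    consequence annotation including frameshift-restoration analysis, and
    biocontrol-index summaries.  A synthetic-data generator emulating a
    hypermutating Bacillus subtilis culture makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
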