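Package: bsaqtl
Title: Bulk-Segregant Candidate-Region Mapping for Bi-Parental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and plumbing for narrowing quantitative trait loci by
    bulk-segregant analysis of pooled sequencing data (BSA-seq). Computes
    per-SNP pool statistics (SNP-index, delta SNP-index, four-base Euclidean
    distance and its fourth power), median+3SD genome-scan thresholds, and
    candidate-region calling and intersection on 1-based inclusive intervals.
    Includes a seeded bi-parental cross simulator (F2 and BC1F2 designs with a
    Haldane map function, tail-bulk selection and pooled read-count emission),
    FASTQ read-quality filters for GBS and re-sequencing libraries, marker
    segregation-pattern classification with distortion/integrity filtering,
    descriptive phenotype statistics, and a file-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    e1071,
    methods,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
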