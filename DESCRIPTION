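Package: methbin
Title: Bin-Based Whole-Genome Bisulfite DMR Analysis of Developing Intestinal Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CpG methylation from whole-genome bisulfite sequencing
    call counts in fixed 200-bp genomic bins, calls maturation- and
    differentiation-associated differentially methylated regions (DMRs) by a
    thresholded bin-difference rule, classifies DMRs by CpG-island status and
    gene-region category into eight groups, performs Fisher's exact gene-set
    enrichment with Bonferroni correction, fits age-adjusted
    methylation-expression regressions with Benjamini-Hochberg FDR control,
    and clusters developmental CpG methylation panels. Ships a synthetic-data
    generator that emulates CGI-structured genomes, beta-binomial bisulfite
    counts, planted DMRs, and methylation-coupled expression, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
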