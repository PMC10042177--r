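Package: tmbpair
Title: Paired-Site Tumour Mutational Burden Estimation and Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumour mutational burden (TMB) from somatic variant
    calls with the Ratio method (callable mutations per megabase of callable
    exome) and with a targeted-panel workflow, and compares paired tumour
    sites (primary versus metastatic) from the same patient. Provides genomic
    interval algebra for building callable-region definitions from BED files
    (merge, gap subtraction, length accounting), two somatic filter regimes
    (whole-genome depth/VAF/known-SNP filtering and panel coverage/allele
    frequency/indel/germline filtering), z-score standardisation across exome
    definitions, high/low classification at a clinical cut-off, paired
    concordance statistics (Spearman correlation with exact permutation
    p-values, exact Wilcoxon signed-rank), ddPCR mutant-allele-fraction and
    qPCR copy-number utilities, and a deterministic synthetic paired-cohort
    generator with full ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
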