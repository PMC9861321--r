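Package: ervpairscan
Title: Strand-Aware Co-Expression Screening of Endogenous Retrovirus Loci
    and Neighboring Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens human endogenous retrovirus (HERV) loci and genes for
    differential expression between interferon-treated and receptor-deficient
    conditions, forms strand-aware HERV-gene pairs within a genomic distance
    window, classifies the concordance pattern of each pair, intersects pair
    sets across contrasts, and summarizes strand bias (exact binomial test),
    per-chromosome distribution, and retroviral superfamily composition.
    Includes a negative-binomial Wald test for count matrices, readers for
    GTF/BED/RepeatMasker annotations and count tables, and a synthetic-data
    generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
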