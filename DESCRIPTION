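Package: ndeg
Title: Cross-Genotype Consensus Differential Expression for
    Nitrogen-Stress Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies candidate nitrogen-stress tolerance genes from
    bulk RNA-seq read counts by consensus over all pairwise contrasts
    between stress-sensitive and stress-tolerant genotypes.  Provides TMM
    normalization and RPKM summaries, a conditional negative-binomial
    exact test with common-dispersion estimation, membership counting
    across the sensitive-by-tolerant comparison grid with exclusion of
    genotype-background differences, hypergeometric gene-set
    over-representation analysis, comparative 2^-ddCT qPCR
    quantification, and a seeded synthetic-data generator with planted
    gene classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
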