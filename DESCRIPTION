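Package: levenemct
Title: Levene-Type Multiple Contrast Tests for Variance Heterogeneity at SNP Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens quantitative-trait loci for variance heterogeneity among
    genotype groups, a signature of unmodelled gene-gene or gene-environment
    interaction. Implements the classical median-based Levene (Brown-Forsythe)
    global test and two multiple contrast alternatives on Levene residuals:
    grand-mean ("Ave") contrasts comparing each genotype group against the
    average of the others, and all pairwise contrasts, both with single-step
    max-t multiplicity adjustment through the joint multivariate t
    distribution. Includes a genome-wide scan driver with the usual
    group-size reporting filters, QQ/Manhattan summary tables, a
    Hardy-Weinberg simulation engine for size and power studies, and readers
    for plain TSV genotype matrices and minimal VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    stats,
    utils,
    vcfR
Suggests:
    car,
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
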