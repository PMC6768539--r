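Package: radpanel
Title: SNP Filtering, Pedigree Reconstruction and Clone Identification
    for Exome-Capture Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control and relationship analysis of
    exome-capture genotyping-by-sequencing (GBS) data in conifer breeding
    programmes. Implements two ordered SNP filtering pipelines driven by
    read depth, allele ratios and haploid (megagametophyte)
    heterozygosity; marker selection for pedigree reconstruction using
    call rate, minor allele frequency, Hardy-Weinberg equilibrium and
    linkage-disequilibrium pruning; exclusion-based trio parentage
    assignment with panel-reduction experiments; and clone
    identification by pairwise genotype mismatch with a ramet versus
    full-sib gap statistic for ranking random SNP panels. A synthetic
    data generator emulates full-sib families, haploid megagametophytes,
    technical replicates, negative-binomial read depth, sequencing
    substitution error and paralog co-capture, so every stage can be
    exercised and validated without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
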