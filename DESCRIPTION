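Package: asekit
Title: Allele-Specific Expression Calling and Two-Locus Population
    Genetics from Allelic Peak Heights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) from per-allele
    fluorescent peak heights measured in matched genomic DNA and cDNA:
    calibrates marker-specific allelic signal bias from known-ratio
    standard mixtures, corrects per-sample allelic ratios, gates
    heterozygotes, excludes mono-allelic amplification, and calls ASE at a
    configurable relative-difference threshold.  Companion tools cover the
    genetic-epidemiology layer of such studies (genotype and allele
    frequency tables, Fisher exact and Hardy-Weinberg exact tests by
    enumeration, two-locus haplotype frequencies by direct counting and
    EM, linkage disequilibrium D, D' and r-squared) and allele-differential
    scanning of promoter variants against IUPAC consensus and position
    weight matrix motifs.  A synthetic-cohort generator with a haplotype
    sampling model, allele-specific expression truth and multiplicative
    peak noise makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
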