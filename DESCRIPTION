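Package: neemomics
Title: Cross-Genotype Marker Discovery and Metabolite-Guided Candidate
    Gene Screening for Neem Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the computational core of a
    neem (Azadirachta indica) multi-omics workflow: microsatellite (SSR)
    mining with canonical motif classification, flank-anchored
    cross-genotype SSR polymorphism calling with concordance
    shortlisting, pileup-based SNP/InDel calling with depth and quality
    filters plus coding-effect annotation and per-kilobase marker
    densities, RPKM expression profiling with tissue-specificity
    partitioning and a Pearson correlation screen against metabolite
    concentrations to nominate biosynthesis candidate genes, and
    internal-standard calibration-curve absolute quantification of
    limonoid metabolites from selected-reaction-monitoring responses.
    A fully seeded synthetic multi-genotype, multi-tissue panel
    generator with machine-readable truth tables makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
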