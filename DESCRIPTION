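Package: haplosweep
Title: Selective-Sweep Scanning and Haplotype Network Analysis for Domestication Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising domestication selective sweeps
    from phased variant data: windowed nucleotide diversity (pi), Hudson F_ST and
    cross-population extended haplotype homozygosity (XP-EHH) scans with empirical
    genome-wide outlier thresholds; gene-region haplotyping under a minor-allele
    frequency filter; median-joining haplotype networks and major-group assignment;
    subpopulation haplotype-frequency shifts; and haplotype-group trait association
    with compact letter displays. Includes a forward-in-time Wright-Fisher simulator
    of a domestication bottleneck with positive selection and partial selfing, so the
    whole pipeline is exercisable on synthetic cohorts with known truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    vcfR,
    jsonlite,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
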