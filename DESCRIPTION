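Package: waspibd
Title: Multi-Scale Population Structure and Dispersal Inference for
    Social Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring dispersal from population-genomic data in
    cooperatively breeding insects, built around the isolation-by-distance
    framework: variant and sample filtering, KING-robust kinship pruning,
    windowed nucleotide diversity and heterozygosity, Weir-Cockerham and
    Hudson F_ST, linearized-F_ST regression on geographic distance with
    Rousset's dispersal-sigma estimator, a mitochondrial-versus-nuclear
    sex-biased-dispersal test, classical MDS on identity-by-state
    distances, minimum-spanning haplotype networks, and a forward-time
    lattice stepping-stone simulator with sex-specific dispersal for
    validating every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
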