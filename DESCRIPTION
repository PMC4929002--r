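Package: madrift
Title: Mutation Accumulation Lines: Drift Simulation, Mutation Calling, and
    Mutational Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mutation accumulation (MA) experiments in which inbred
    lines are propagated at small population size so that genetic drift, not
    selection, governs the fate of new mutations. Simulates MA lines under
    neutral Wright-Fisher drift with known ground truth, calls spontaneous
    mutations from per-site allele-count (pileup) tables using a six-clause
    filter, infers the effective population size (2Ne) from the mutant
    allele-frequency spectrum by simulation-based maximum likelihood,
    estimates per-line mutation rates, and partitions quantitative-trait
    variance into mutational and environmental components to compare
    mutational heritability and the ratio of mutational to standing genetic
    variance against neutral and mutation-selection-balance expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    data.table,
    lme4,
    mclust,
    jsonlite,
    yaml,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
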