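Package: rarepower
Title: Simulation-Based Power Evaluation of Gene-Based Rare-Variant Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates case-control sequence data at gene-sized loci under
    explicit genetic architectures and evaluates a battery of gene-based
    rare-variant association tests. A phased haplotype reference panel is
    simulated by a Li-and-Stephens style copying model, expanded to large
    sample sizes, and calibrated against an exome-like site frequency
    spectrum by rejection thinning. Causal variants are assigned per-allele
    relative risks from configurable frequency-by-effect-size maps under a
    liability-threshold disease model, and cohorts are drawn by
    prevalence-constrained rejection sampling. Eleven gene-based tests
    (CMC, VT, FRQWGT, WILCOX-WSS, KBAC, BURDEN, UNIQ, C-ALPHA, SKAT,
    SKAT-O, MiST) plus single-variant Fisher's exact are implemented from
    scratch behind a uniform interface, with adaptive permutation p-values
    and exact mixture-of-chi-square tail probabilities. Downstream tooling
    quantifies power, type-I-error calibration, between-test concordance,
    combined single-variant/gene-based sensitivity, and greedy composite
    test selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
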