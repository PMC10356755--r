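Package: seedbankcoevo
Title: Molecular Evolution of Bacteria-Phage Coevolution with a Seed Bank
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled-population sequencing of experimentally
    coevolving bacteria and phage under a dormancy (seed bank) manipulation.
    Implements frequency-weighted gene multiplicity and relative multiplicity,
    permutational two-sample Kolmogorov-Smirnov tests, Bray-Curtis principal
    coordinate ordination with two-way PERMANOVA on mutated-gene composition,
    and host-phage mutation-trajectory correlation analysis against a
    permuted-time null. Includes closed-form arithmetic of the serial-transfer
    design (adsorption rate constants, generation counts, seed-bank dilution
    expectations) and a synthetic Pool-seq trajectory generator that emulates
    the 2x2 factorial (seed bank x phage) experiment so the full pipeline runs
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
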