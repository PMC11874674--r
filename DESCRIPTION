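Package: clutchkin
Title: Parentage and Sibship Reconstruction for Brood-Parasite Clutches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers mating patterns of the brood-parasitic cuckoo catfish
    (Synodontis multipunctatus) from embryo genotypes alone: microsatellite
    marker diagnostics (allele frequencies, heterozygosities, exact
    Hardy-Weinberg tests, exclusion probabilities), maximum-likelihood dyadic
    kinship classification with Monte-Carlo likelihood-ratio tests,
    minimum-parent parsimony reconstruction of clutch sibships, mitochondrial
    matriline overlay to separate dams from sires, and classification of
    clutches into mating scenarios. Includes a Mendelian clutch simulator with
    ground-truth pedigrees so every stage can be exercised and validated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
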