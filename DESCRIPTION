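Package: phenopop
Title: Population Genetics for Mixed-Ploidy Allele-Phenotype Marker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis chain for codominant microsatellite (SSR) genotypes
    scored as allele phenotypes (presence/absence, dosage unknown), the
    standard coding for collections that mix ploidy levels. Provides
    codominant-to-binary transformation with per-locus missingness handling,
    per-locus diversity indices (observed, mean and effective allele numbers,
    rare-allele counts), the Dice genetic distance with locus bootstraps,
    discriminant analysis of principal components (DAPC) with a K-means/BIC
    scan, modal-K selection and a-score choice of retained components,
    distance-based two-level AMOVA with PhiPT and permutation tests, temporal
    allele-frequency shift detection, and a forward Wright-Fisher simulator
    of mixed-ploidy subpopulations under polysomic inheritance used to test
    whether ploidy level biases the detection of genetic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    MASS,
    multcomp,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
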