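Package: paleoflow
Title: Population Structure, Admixture Modelling and Admixture Dating for
    Pseudo-Haploid Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the standard ancient-DNA population-genetic workflow
    on pseudo-haploid genotype data: EIGENSTRAT input/output with
    authenticity gating, kinship screening and group age labelling;
    f2/f3/f4 statistics with weighted block-jackknife standard errors;
    outgroup-f3 summaries (multidimensional scaling, neighbour-joining
    trees) and projection principal component analysis; qpWave-style
    matrix rank tests and qpAdm-style admixture proportion estimation;
    admixture-graph fitting with greedy population addition; and
    admixture dating from the exponential decay of weighted allele
    covariance with genetic distance. Includes a coalescent-free
    drift simulator (Balding-Nichols frequencies on an admixture graph,
    exponential ancestry tracts) so every stage can be validated by
    parameter recovery on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
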