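Package: heterofit
Title: Biparental Genetic Heterogeneity and Seedling Fitness from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links seedling fitness to the genetic heterogeneity of its
    parents in admixed tree populations. Provides readers and writers for
    diploid codominant (microsatellite) genotype tables, Bayesian admixture
    clustering under the correlated allele-frequency (F) model with Evanno
    delta-K model selection, likelihood-based categorical paternity
    assignment with simulation-calibrated delta confidence and Mendelian
    exclusion, maximum-likelihood pairwise relatedness, the Rogers-distance
    ancestry statistic qdis and its Fst-weighted counterpart fdis, Cox
    proportional-hazards survival modelling of seedling cohorts, a Bayesian
    normal mixed model for relative growth rate, and a forward simulator of
    admixed adults, matings and seedling fitness that supplies known truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
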