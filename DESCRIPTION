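Package: migragen
Title: Migration Genomics of GPS-Collared Ungulates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking individual migratory
    behaviour of GPS-collared ungulates to genome-wide SNP variation and
    genetic ancestry. Classifies animals as migrants or residents from
    telemetry via seasonal range overlap (kernel utilization distributions,
    95% isopleths) and net-squared-displacement movement-model selection;
    estimates population structure (PCA, maximum-likelihood admixture with
    cross-validation over K, Weir-Cockerham F_ST); runs univariate
    linear-mixed-model SNP association with a relatedness (kinship) matrix,
    Wald tests, Bonferroni correction, genomic inflation factors and
    per-SNP proportion of variance explained; and regresses migratory
    behaviour on admixture proportions with ecotype random effects. Includes
    a synthetic-data generator (Balding-Nichols genotypes with admixture and
    causal loci, plus daily GPS tracks) so every stage is testable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    minpack.lm,
    vcfR,
    yaml,
    jsonlite,
    lme4
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
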