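Package: enviroGP
Title: Multi-Environment Genomic Prediction with Environmental Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-environment genomic prediction in plant breeding
    programs using reaction-norm models. Parses and quality-filters SNP
    genotypes in HapMap format, builds the genomic relationship matrix,
    derives environmental covariates from daily weather over crop phenology
    windows, assembles environmental kernels (Omega proportional to WW'),
    and fits multi-kernel Bayesian GBLUP models with genotype-by-environment
    interaction terms via a Gibbs sampler. Includes cross-validation designs
    for predicting untested environments and untested lines (random,
    covariate-selected, and leave-one-environment-out training sets),
    Fisher-z model comparison with Tukey grouping, and a synthetic-data
    generator with known ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
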