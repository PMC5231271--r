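Package: pleioscan
Title: Multivariate Genome-Wide Association Tests for Phenotypes with Mixed
    Measurement Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase multivariate association testing for pleiotropic loci
    when the phenotypes mix continuous, binary, and ordinal measurement scales.
    Phase one fits scale-matched marginal regressions (linear, logistic,
    cumulative logit) per SNP and phenotype; phase two combines the marginal
    p-values with the Fisher statistic, whose gamma null distribution is
    moment-matched using latent-model correlations between phenotypes
    (Kendall sine, Lord biserial, tetrachoric, polyserial, polychoric).
    Includes the full simulation machinery for correlation-estimator accuracy,
    covariance conservativeness, type-I error, and power studies, plus file
    I/O for phenotype tables and VCF or additive-coded genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    vcfR,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
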