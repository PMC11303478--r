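Package: geisim
Title: Simulating Genotype-by-Environment Interaction with Multiplicative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genotype-by-environment interaction (GEI) for plant
    breeding research using reduced-rank multiplicative models. A hypothetical
    target population of environments (TPE) is represented by a
    between-environment genetic variance matrix with gamma-distributed
    genetic variances and a structured-noise correlation matrix of
    controllable rank and skew. GE effects are constructed from environmental
    covariates and genotype slopes obtained by eigendecomposition, embedded in
    a linear mixed model to generate plot-level multi-environment-trial (MET)
    datasets, and summarised with measures of variance explained (main
    effect, interaction, non-crossover, crossover), expected accuracy and
    MET-TPE alignment. A recurrent breeding-programme simulator compares
    phenotypic and genomic selection under different levels of GEI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
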