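Package: gsei
Title: Genomic Selection of Gene-Bank Donors with GBLUP and Expected Improvement
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying promising donor accessions from a genotyped
    gene-bank panel using genomic prediction. Implements single-component
    GBLUP with restricted maximum likelihood (EMMA-style spectral solver),
    the VanRaden genomic relationship matrix, broad-sense heritability from
    replicated trials, the expected-improvement (EI) selection criterion with
    frequentist (mixed-model-equation) or MCMC (Gibbs sampler) uncertainty,
    top-k selection with overlap bookkeeping, equally spaced control sets,
    repeated k-fold cross-validation, year-to-year forward validation,
    phenotypic and genetic correlation matrices across environments, a
    synthetic-data generator with known ground truth emulating a
    multi-environment gene-bank field study, and a configuration-driven
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr
Config/testthat/edition: 3
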