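Package: deltamed
Title: Latent Dementia Phenotype Construction and Serum-Protein Mediation
    Screening by Structural Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a latent dementia phenotype (delta, the
    disability-weighted fraction of general cognitive performance) from a
    bifactor structural equation model, scoring subjects by regression-method
    factor weights with Grice determinacy diagnostics, validating the
    phenotype against clinical severity and diagnosis (ROC/AUC), and
    screening serum-protein panels as candidate mediators of age's direct
    effect on the phenotype (product-of-coefficients indirect effects, Sobel
    tests, a Bonferroni significance gate, and a four-class protein
    taxonomy).  Includes a covariance-structure estimation engine (maximum
    likelihood and full-information maximum likelihood for incomplete data,
    fit indices, nested-model and multi-group difference tests), a biomarker
    preprocessing chain (outlier trimming, log-normalization,
    standardization, batch residualization), split-half generalizability
    testing, and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
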