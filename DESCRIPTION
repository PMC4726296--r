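Package: rmlmgwas
Title: Random-SNP-Effect Mixed Linear Models for Multi-Locus GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association mapping with a random-SNP-effect mixed
    linear model. A single-locus scan profiles the restricted likelihood in
    one variance ratio per marker using Woodbury rank-one updates under a
    polygenic background fixed once from the null model (P3D), reports BLUP
    effects with Wald tests, and applies a modified Bonferroni threshold
    based on the effective number of independent markers. A second stage
    preselects markers at a lenient threshold, prunes them positionally,
    classifies them as fixed or random by a likelihood ratio test, fits all
    survivors jointly by EM empirical Bayes shrinkage, and declares
    quantitative trait nucleotides at LOD >= 3. A fixed-effect (EMMA-style)
    scan is included as a baseline, together with a simulation and
    evaluation harness (power, mean squared error, Type 1 error, ROC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
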