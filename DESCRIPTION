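Package: epiage
Title: Comparative Epigenetic Aging Rates from Methylation Beta Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-CpG epigenetic aging rates (methylation change per
    year) from beta-value matrices in two cohorts reared in different
    environments, tests age-by-environment interactions with massively
    parallel per-probe linear models, classifies slope pairs into angular
    octants, quantifies cohort rate ratios with zero-intercept regression,
    performs probe-set enrichment against a background probe universe, and
    trains and applies elastic-net epigenetic clocks restricted to autosomal
    probes. Includes a synthetic two-cohort methylome generator with known
    per-site ground truth for parameter-recovery testing, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    fgsea,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
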