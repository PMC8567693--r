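Package: placmed
Title: Placental Mediation of Maternal Blood-Pressure Polygenic Scores on Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how maternal blood-pressure-increasing polygenic
    scores (PGS) affect offspring birth weight through placental growth in
    mother-father-child trio cohorts. Implements variant quality control, LD
    clumping and p-value thresholding for PGS construction from GWAS summary
    statistics, maternal transmitted/non-transmitted haplotype allele-count
    decomposition from phased genotypes, reference-chart standardization of
    perinatal weights, smoothing-spline estimation of weekly fetal growth
    velocity from serial ultrasound, linear causal mediation analysis with
    quasi-Bayesian Monte Carlo intervals and sensitivity analysis for
    sequential ignorability, and a fully synthetic trio-cohort generator with
    retained ground truth so every stage is testable without access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
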