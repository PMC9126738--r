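Package: wheatphys
Title: Photosynthetic CO2-Response Fitting and Panel Phenotyping for Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Farquhar-von Caemmerer-Berry (FvCB) model to A/ci
    gas-exchange curves by exhaustive enumeration of ordered limitation-state
    assignments (Rubisco, RuBP regeneration, triose-phosphate utilization)
    with admissibility checking and co-limited "swinging point" resolution;
    computes derived leaf traits (limitation transitions, stomatal
    limitation, intrinsic water-use efficiency, per-nitrogen rates, yield
    components); provides the statistics stage used in two-line and panel
    comparisons (Tukey-fence outlier filtering, Shapiro-Wilk/F/t cascade,
    covariate-adjusted genotype means, within- and cross-environment Pearson
    correlation matrices); computes windowed identity-by-state SNP similarity
    between lines from VCF input; and generates synthetic gas-exchange
    curves, panel trait tables and variant tables for testing all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    emmeans,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
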