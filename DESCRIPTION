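Package: cortexARI
Title: Attenuation of Transcriptomic Regional Identity in Multi-Region
    Brain Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and tests attenuation of regional identity (ARI) in
    multi-region, multi-subject brain expression data: paired Wilcoxon
    signed-rank counting of differentially expressed genes between cortical
    region pairs, a subject-level permutation test for reduced between-region
    differences in cases versus controls, a complementary age-matched
    bootstrap, extraction of the genes driving the attenuation via a
    permutation-occurrence filter, and comparison of regional versus
    whole-cortex differential-expression effect sizes by total least squares
    (orthogonal) regression. Includes a synthetic multi-region cohort
    generator with known anterior-posterior gradient structure, plus the
    expression QC steps (CPM/length filtering, log2-CPM normalization,
    PC/connectivity sample outlier detection, mixed-model covariate
    regression) that produce the regressed matrix the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
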