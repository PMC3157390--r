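Package: replix
Title: Replication Expectations for Published Genetic Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and evaluating replication of published
    SNP-trait associations in a new cohort. Curates a GWAS-catalog-style
    association list (p-value, effect and ancestry filters, deduplication,
    LD pruning, proxy-SNP selection, strand checks), assigns case/control
    status from self-reported survey answers with onset, sex, smoking and
    incidence-based age restrictions, runs one-sided Cochran-Armitage
    trend and Wald tests in the published direction, computes analytic
    trend-test power adjusted for phenotype misclassification, proxy r2
    and winner's-curse effect-size inflation, and compares observed
    replication counts with exact Poisson-binomial prediction intervals.
    Includes a synthetic-data generator so the whole pipeline can be
    exercised and calibrated without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
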