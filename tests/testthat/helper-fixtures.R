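# In-code fixtures shared across test files.

catalog_row <- function(snp_id = "rs1", phenotype = "trait",
                        risk_allele = "A", other_allele = "G",
                        raf = 0.3, effect = 1.3,
                        trait_type = "binary", p_value = 1e-9,
                        ancestry = "European", study_id = "PMID00001",
                        n_cases = 1000L, n_controls = 2000L,
                        single_snp = TRUE, includes_cohort = FALSE) {
  data.frame(snp_id = snp_id, phenotype = phenotype,
             risk_allele = risk_allele, other_allele = other_allele,
             raf = raf, effect = effect, trait_type = trait_type,
             p_value = p_value, ancestry = ancestry, study_id = study_id,
             n_cases = n_cases, n_controls = n_controls,
             single_snp = single_snp, includes_cohort = includes_cohort)
}

# expand a 2x3 genotype-count table into per-subject dosage/status vectors
expand_counts <- function(case_counts, control_counts) {
  g <- c(rep(0:2, case_counts), rep(0:2, control_counts))
  y <- c(rep(TRUE, sum(case_counts)), rep(FALSE, sum(control_counts)))
  list(g = g, y = y)
}

# independent textbook Cochran-Armitage trend chi-square for a 2x3 table
# (coded from the standard formula, separate from the package's score form)
ca_trend_chisq_oracle <- function(case_counts, control_counts) {
  x <- 0:2
  r <- case_counts
  n <- case_counts + control_counts
  R <- sum(r); N <- sum(n)
  num <- N * (N * sum(x * r) - R * sum(x * n))^2
  den <- R * (N - R) * (N * sum(x^2 * n) - sum(x * n)^2)
  num / den
}

default_sim_config <- function(seed = 42, n_subjects = 2000,
                               e_case = 0.05, e_control = 0.05, ...) {
  assoc <- data.frame(
    snp_id = c("rsB1", "rsB2", "rsQ1"),
    phenotype = c("disease_a", "disease_b", "height"),
    raf = c(0.3, 0.2, 0.4),
    effect = c(1.3, 1.5, 0.2),
    trait_type = c("binary", "binary", "quantitative"),
    prevalence = c(0.1, 0.05, NA),
    class = c("autoimmune", "autoimmune", "anthropometric"))
  sim_config(seed = seed, n_subjects = n_subjects, associations = assoc,
             e_case = e_case, e_control = e_control, ...)
}
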