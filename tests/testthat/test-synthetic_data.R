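test_that("generators are deterministic given the seed", {
  cfg <- default_sim_config(seed = 123, n_subjects = 300)
  a <- gen_catalog(cfg); b <- gen_catalog(cfg)
  expect_identical(a, b)
  ca <- gen_cohort(cfg); cb <- gen_cohort(cfg)
  expect_identical(ca, cb)
  sa <- gen_surveys(cfg, ca$phenotypes)
  sb <- gen_surveys(cfg, cb$phenotypes)
  expect_identical(sa, sb)
  # a different seed changes the draws
  expect_false(identical(
    gen_cohort(default_sim_config(seed = 124, n_subjects = 300))$genotypes,
    ca$genotypes))
})

test_that("synthetic catalog rows realize their labelled curation outcomes", {
  cfg <- default_sim_config(seed = 31)
  syn <- gen_catalog(cfg)
  catalog <- syn$catalog[setdiff(names(syn$catalog), "expected_outcome")]
  res <- curate_catalog(catalog, syn$ld, syn$platform,
                        reference_freqs = syn$reference_freqs)
  expected <- setNames(syn$catalog$expected_outcome,
                       paste(syn$catalog$snp_id, syn$catalog$study_id))
  kept_keys <- paste(res$curated$snp_id, res$curated$study_id)
  dropped_keys <- paste(res$dropped$snp_id, res$dropped$study_id)

  for (key in names(expected)) {
    outcome <- expected[[key]]
    if (outcome %in% c("retained", "review")) {
      expect_true(key %in% kept_keys, label = paste(key, "retained"))
    } else if (outcome == "proxy") {
      expect_true(key %in% kept_keys)
      expect_lt(res$curated$proxy_r2[kept_keys == key], 1)
    } else if (outcome %in% c("filtered", "dropped")) {
      expect_true(key %in% dropped_keys, label = paste(key, "dropped"))
    } else {  # dedup_loser / ld_pruned: silently pruned, not retained
      expect_false(key %in% kept_keys)
    }
  }
  # the ambiguous-allele row is flagged for review
  expect_true("rsAMBIG" %in% res$review$snp_id)
  # the proxied row points at the highest-r2 proxy
  expect_equal(res$curated$test_snp[res$curated$snp_id == "rsOFFPLAT"],
               "rsPROXY1")
  expect_true(all(res$curated$proxy_r2 >= 0.5))
})

test_that("cohort generator recovers its own parameters", {
  assoc <- data.frame(snp_id = c("rs_null", "rs_eff"),
                      phenotype = c("d_null", "d_eff"),
                      raf = c(0.3, 0.3), effect = c(1, 1.5),
                      trait_type = "binary", prevalence = c(0.1, 0.1))
  cfg <- sim_config(seed = 77, n_subjects = 20000, associations = assoc,
                    e_case = 0, e_control = 0)
  cohort <- gen_cohort(cfg)

  # HWE allele frequency
  expect_lt(abs(mean(cohort$genotypes[, "rs_eff"]) / 2 - 0.3),
            3 * sqrt(0.3 * 0.7 / (2 * 20000)))

  ph <- cohort$phenotypes
  eff <- ph[ph$association == "rs_eff", ]
  expect_lt(abs(mean(eff$true_status) - 0.1),
            3 * sqrt(0.1 * 0.9 / 20000))
  fit <- or_with_ci(cohort$genotypes[eff$subject_id, "rs_eff"],
                    eff$true_status)
  expect_lt(abs(fit$log_or - log(1.5)) / fit$se, 3)

  nul <- ph[ph$association == "rs_null", ]
  fit0 <- or_with_ci(cohort$genotypes[nul$subject_id, "rs_null"],
                     nul$true_status)
  expect_lt(abs(fit0$log_or) / fit0$se, 3)
})

test_that("quantitative traits carry the configured slope", {
  assoc <- data.frame(snp_id = "rs_q", phenotype = "ht", raf = 0.4,
                      effect = 0.25, trait_type = "quantitative",
                      prevalence = NA)
  cfg <- sim_config(seed = 5, n_subjects = 8000, associations = assoc)
  cohort <- gen_cohort(cfg)
  ph <- cohort$phenotypes
  res <- wald_linear_test(cohort$genotypes[ph$subject_id, "rs_q"],
                          ph$trait, "+")
  expect_lt(abs(res$effect_estimate - 0.25) / res$se, 3)
})

test_that("proxy SNPs hit their target r2", {
  assoc <- data.frame(snp_id = "rs_t", phenotype = "d", raf = 0.3,
                      effect = 1.2, trait_type = "binary",
                      prevalence = 0.1)
  proxy <- data.frame(snp_id = "rs_t", proxy_id = "rs_p",
                      target_r2 = 0.6, proxy_raf = 0.35)
  cfg <- sim_config(seed = 9, n_subjects = 50000, associations = assoc,
                    proxy_specs = proxy)
  cohort <- gen_cohort(cfg)
  r2 <- stats::cor(cohort$genotypes[, "rs_t"],
                   cohort$genotypes[, "rs_p"])^2
  expect_lt(abs(r2 - 0.6), 0.02)

  # infeasible r2 names the feasible range
  bad <- data.frame(snp_id = "rs_t", proxy_id = "rs_b",
                    target_r2 = 0.9, proxy_raf = 0.9)
  cfg_bad <- sim_config(seed = 9, n_subjects = 100, associations = assoc,
                        proxy_specs = bad)
  expect_error(gen_cohort(cfg_bad), "unattainable")
})

test_that("survey noise fractions are realized", {
  cfg <- default_sim_config(seed = 13, n_subjects = 10000,
                            p_uncertain = 0.1, p_inconsistent = 0.05)
  cohort <- gen_cohort(cfg)
  surveys <- gen_surveys(cfg, cohort$phenotypes)
  defn <- phenotype_definition("disease_a",
                               c("q_disease_a_1", "q_disease_a_2"))
  out <- assign_case_control(surveys, defn)
  n <- length(unique(surveys$subject_id[grepl("disease_a",
                                              surveys$question_id)]))
  n_unc <- sum(out$reason == "uncertain_only")
  n_inc <- sum(out$reason == "inconsistent")
  expect_lt(abs(n_unc - 0.1 * n), 3 * sqrt(0.1 * 0.9 * n))
  expect_lt(abs(n_inc - 0.05 * n), 3 * sqrt(0.05 * 0.95 * n))

  # with no noise nobody is excluded for uncertainty or inconsistency
  cfg0 <- default_sim_config(seed = 13, n_subjects = 1000,
                             p_uncertain = 0, p_inconsistent = 0)
  c0 <- gen_cohort(cfg0)
  s0 <- gen_surveys(cfg0, c0$phenotypes)
  out0 <- assign_case_control(s0, defn)
  expect_equal(sum(out0$reason %in% c("uncertain_only", "inconsistent")),
               0)
  # and assignments agree with the generator's reported status
  ph0 <- c0$phenotypes[c0$phenotypes$phenotype == "disease_a", ]
  merged <- merge(out0, ph0, by = "subject_id")
  expect_true(all(merged$status[merged$reported_status] == "case"))
  expect_true(all(merged$status[!merged$reported_status] == "control"))
})

test_that("end-to-end synthetic pipeline produces a coherent summary", {
  assoc <- data.frame(
    snp_id = sprintf("rs%03d", 1:8),
    phenotype = sprintf("d%03d", 1:8),
    raf = rep(c(0.2, 0.3, 0.4, 0.5), 2),
    effect = rep(c(1.2, 1.4), each = 4),
    trait_type = "binary",
    prevalence = 0.2,
    class = rep(c("met", "auto"), 4))
  cfg <- sim_config(seed = 21, n_subjects = 4000, associations = assoc,
                    e_case = 0, e_control = 0)
  cohort <- gen_cohort(cfg)
  curated <- assoc
  curated$test_snp <- curated$snp_id
  ph <- cohort$phenotypes
  ph$reported_status <- ph$true_status
  results <- test_curated_associations(curated, cohort$genotypes, ph)
  expect_true(all(results$testable))
  powers <- data.frame(
    snp_id = assoc$snp_id,
    power = vapply(seq_len(8), function(i)
      power_trend_test(sum(ph$true_status[ph$association == assoc$snp_id[i]]),
                       sum(!ph$true_status[ph$association == assoc$snp_id[i]]),
                       assoc$raf[i], assoc$effect[i], 0.2,
                       alpha = 0.05, sided = "one", e_case = 0,
                       e_control = 0)$power, numeric(1)),
    class = assoc$class)
  summ <- replication_summary(results, powers)
  overall <- summ[summ$class == "overall", ]
  expect_equal(overall$attempts, 8)
  expect_true(overall$observed >= 0 && overall$observed <= 8)
  expect_equal(sum(summ$expected[summ$class != "overall"]),
               overall$expected)
})
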