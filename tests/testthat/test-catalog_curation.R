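test_that("eligibility filters drop the documented entry classes", {
  entries <- rbind(
    catalog_row("rs_keep", p_value = 1e-8),
    catalog_row("rs_weak_p", p_value = 1e-6),
    catalog_row("rs_no_eff", effect = NA_real_),
    catalog_row("rs_haplo", single_snp = FALSE),
    catalog_row("rs_asian", ancestry = "East Asian"),
    catalog_row("rs_self", includes_cohort = TRUE))
  kept <- filter_entries(entries)
  expect_identical(kept$snp_id, "rs_keep")
  dropped <- attr(kept, "dropped")
  expect_setequal(
    dropped$drop_reason,
    c("p_above_threshold", "no_effect_size", "haplotype_association",
      "non_european", "includes_cohort"))
  # boundary: p exactly at the threshold is retained
  expect_equal(nrow(filter_entries(catalog_row(p_value = 1e-7))), 1)
})

test_that("deduplication keeps the largest study, with deterministic ties", {
  entries <- rbind(
    catalog_row("rs1", study_id = "PMIDaaa", n_cases = 500L, p_value = 1e-10),
    catalog_row("rs1", study_id = "PMIDbbb", n_cases = 2000L, p_value = 1e-8),
    catalog_row("rs2", study_id = "PMIDccc"))
  out <- deduplicate_entries(entries)
  expect_equal(nrow(out), 2)
  expect_equal(out$study_id[out$snp_id == "rs1"], "PMIDbbb")

  # tie on case count: smaller p wins
  tie <- rbind(
    catalog_row("rs1", study_id = "PMIDa", n_cases = 1000L, p_value = 1e-8),
    catalog_row("rs1", study_id = "PMIDb", n_cases = 1000L, p_value = 1e-11))
  expect_equal(deduplicate_entries(tie)$study_id, "PMIDb")

  # same SNP, different phenotypes: not duplicates
  two_ph <- rbind(catalog_row("rs1", phenotype = "a"),
                  catalog_row("rs1", phenotype = "b"))
  expect_equal(nrow(deduplicate_entries(two_ph)), 2)
  expect_identical(deduplicate_entries(entries[3, ]), entries[3, ])
})

test_that("LD pruning keeps one association per connected component", {
  ld <- data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
                   r2 = c(0.15, 0.15))
  # r2(rs1, rs3) missing -> 0, but the component is transitively joined
  entries <- rbind(
    catalog_row("rs1", p_value = 1e-9),
    catalog_row("rs2", p_value = 1e-8),
    catalog_row("rs3", p_value = 1e-10))
  out <- prune_ld(entries, ld)
  expect_equal(out$snp_id, "rs3")  # single study: smallest p wins

  # below the blocking threshold both survive
  weak <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.05)
  expect_equal(nrow(prune_ld(entries[1:2, ], weak)), 2)

  # across studies the larger case count wins even with a larger p
  cross <- rbind(
    catalog_row("rs1", study_id = "PMIDa", n_cases = 500L, p_value = 1e-12),
    catalog_row("rs2", study_id = "PMIDb", n_cases = 5000L, p_value = 1e-8))
  expect_equal(prune_ld(cross, ld)$snp_id, "rs2")

  # pruning is per-phenotype: the same pair in different traits survives
  two_ph <- rbind(catalog_row("rs1", phenotype = "a"),
                  catalog_row("rs2", phenotype = "b"))
  expect_equal(nrow(prune_ld(two_ph, ld)), 2)
})

test_that("LD components match a brute-force graph oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    snps <- paste0("rs", seq_len(n))
    pairs <- t(combn(snps, 2))
    r2 <- stats::runif(nrow(pairs))
    ld <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2], r2 = r2)
    entries <- do.call(rbind, lapply(seq_len(n), function(i)
      catalog_row(snps[i], p_value = 10^-stats::runif(1, 8, 12))))
    out <- prune_ld(entries, ld, r2_block = 0.5)

    # oracle: label propagation to a fixed point over the adjacency matrix
    adj <- matrix(FALSE, n, n, dimnames = list(snps, snps))
    for (k in seq_len(nrow(ld)))
      if (ld$r2[k] >= 0.5)
        adj[ld$snp_a[k], ld$snp_b[k]] <- adj[ld$snp_b[k], ld$snp_a[k]] <- TRUE
    lab <- seq_len(n)
    repeat {
      old <- lab
      for (i in seq_len(n)) for (j in seq_len(n))
        if (adj[i, j]) lab[c(i, j)] <- min(lab[i], lab[j])
      if (identical(old, lab)) break
    }
    expect_equal(nrow(out), length(unique(lab)))
    # at most one survivor per component
    expect_false(any(duplicated(lab[match(out$snp_id, snps)])))
  }
})

test_that("proxy selection follows platform presence, call rate and r2", {
  platform <- data.frame(snp_id = c("rs_on", "rs_low", "rs_prox1",
                                    "rs_prox2"),
                         call_rate = c(0.995, 0.95, 0.999, 0.999))
  ld <- data.frame(snp_a = c("rs_off", "rs_off", "rs_low", "rs_far"),
                   snp_b = c("rs_prox1", "rs_prox2", "rs_prox1", "rs_weak"),
                   r2 = c(0.6, 0.55, 0.7, 0.4))
  entries <- rbind(catalog_row("rs_on"), catalog_row("rs_off"),
                   catalog_row("rs_low"), catalog_row("rs_far"))
  out <- select_proxies(entries, platform, ld)
  expect_equal(out$test_snp[out$snp_id == "rs_on"], "rs_on")
  expect_equal(out$proxy_r2[out$snp_id == "rs_on"], 1)
  # off-platform: best eligible proxy
  expect_equal(out$test_snp[out$snp_id == "rs_off"], "rs_prox1")
  expect_equal(out$proxy_r2[out$snp_id == "rs_off"], 0.6)
  # on-platform but poorly called: proxied like an absent SNP
  expect_equal(out$test_snp[out$snp_id == "rs_low"], "rs_prox1")
  # no proxy above 0.5: dropped with a reason
  expect_false("rs_far" %in% out$snp_id)
  expect_equal(attr(out, "dropped")$drop_reason, "no_platform_snp_or_proxy")
  expect_true(all(out$proxy_r2 >= 0.5))
})

test_that("strand checking applies the frequency-band and ambiguity rules", {
  expect_equal(check_strand("A", "G", 0.2, 0.3), "confirmed")
  expect_equal(check_strand("A", "G", 0.8, 0.7), "confirmed")
  expect_equal(check_strand("A", "T", 0.2, 0.3), "manual_review")
  expect_equal(check_strand("C", "G", 0.2, 0.3), "manual_review")
  expect_equal(check_strand("A", "G", 0.5, 0.5), "manual_review")
  expect_equal(check_strand("A", "G", 0.2, 0.7), "manual_review")
  expect_equal(check_strand("A", "G", 0.2, NA), "manual_review")
  # frequencies exactly at the band edges do not match
  expect_equal(check_strand("A", "G", 0.35, 0.2), "manual_review")
  expect_equal(check_strand("A", "G", 0.2, 0.65), "manual_review")
  expect_equal(check_strand("A", "G", 0.2, 0.3, unresolvable = TRUE),
               "undetermined")
  expect_error(check_strand("A", "N", 0.2, 0.3), "invalid allele")
})

test_that("full curation is idempotent and order-insensitive", {
  cfg <- default_sim_config()
  syn <- gen_catalog(cfg)
  cat1 <- syn$catalog[setdiff(names(syn$catalog), "expected_outcome")]
  run <- function(catalog) {
    curate_catalog(catalog, syn$ld, syn$platform,
                   reference_freqs = syn$reference_freqs)
  }
  first <- run(cat1)
  second <- run(first$curated[names(cat1)])
  expect_equal(second$curated[names(cat1)], first$curated[names(cat1)],
               ignore_attr = TRUE)
  expect_equal(nrow(second$dropped), 0)

  # filter and dedup commute
  f_then_d <- deduplicate_entries(filter_entries(cat1))
  d_then_f <- filter_entries(deduplicate_entries(cat1))
  expect_setequal(paste(f_then_d$snp_id, f_then_d$study_id),
                  paste(d_then_f$snp_id, d_then_f$study_id))
})

test_that("TSV readers parse the documented formats and flag bad rows", {
  dir <- withr::local_tempdir()
  catalog <- rbind(catalog_row("rs1"), catalog_row("rs2", effect = NA))
  path <- file.path(dir, "catalog.tsv")
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  back <- read_catalog(path)
  expect_equal(back$effect, c(1.3, NA))
  expect_equal(back$p_value, catalog$p_value)
  expect_true(is.logical(back$single_snp))

  bad <- catalog
  bad$p_value <- c("1e-9", "oops")
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  expect_error(read_catalog(path), "row 2.*p_value")

  ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.4)
  ld_path <- file.path(dir, "ld.tsv")
  utils::write.table(ld, ld_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_ld_table(ld_path)$r2, 0.4)

  pl <- data.frame(snp_id = "rs1", call_rate = 0.999)
  pl_path <- file.path(dir, "platform.tsv")
  utils::write.table(pl, pl_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_platform_manifest(pl_path)$call_rate, 0.999)
})
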