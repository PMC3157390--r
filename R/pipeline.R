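# End-to-end convenience layer: run every curated association's test
# against a cohort and summarize observed versus expected replications.

#' Test all curated associations in a cohort
#'
#' For each curated association, runs the one-sided trend test (binary
#' traits) or Wald linear test (quantitative traits) of the phenotype on
#' the dosage of the association's test SNP, in the published direction
#' (risk-increasing for OR > 1 or beta > 0).
#'
#' @param curated Curated catalog (rows with \code{snp_id},
#'   \code{test_snp}, \code{trait_type}, \code{effect},
#'   \code{phenotype}).
#' @param genotypes Subjects-by-SNPs dosage matrix (risk-allele counts),
#'   with column names matching \code{test_snp} and row names matching
#'   subject ids.
#' @param phenotypes Data frame with \code{subject_id},
#'   \code{phenotype}, and \code{reported_status} (logical) or
#'   \code{trait} (numeric), as produced by [gen_cohort()] or by the
#'   phenotyping stage.
#' @param alpha_rep,alpha_dir Classification thresholds (see
#'   [classify_replication()]).
#' @return Data frame: one row per association with \code{snp_id},
#'   \code{test_snp}, \code{statistic}, \code{p_one_sided},
#'   \code{testable}, \code{call}.
#' @export
test_curated_associations <- function(curated, genotypes, phenotypes,
                                      alpha_rep = 0.05, alpha_dir = 0.5) {
  rows <- lapply(seq_len(nrow(curated)), function(i) {
    entry <- curated[i, ]
    snp <- if ("test_snp" %in% names(entry)) entry$test_snp
           else entry$snp_id
    ph <- phenotypes[phenotypes$phenotype == entry$phenotype, ,
                     drop = FALSE]
    if (!snp %in% colnames(genotypes) || nrow(ph) == 0)
      return(data.frame(snp_id = entry$snp_id, test_snp = snp,
                        statistic = NA_real_, p_one_sided = NA_real_,
                        testable = FALSE, call = NA_character_))
    g <- genotypes[ph$subject_id, snp]
    direction <- if (entry$trait_type == "binary") {
      if (entry$effect >= 1) "+" else "-"
    } else {
      if (entry$effect >= 0) "+" else "-"
    }
    res <- if (entry$trait_type == "binary")
      trend_score_test(g, ph$reported_status, direction)
    else
      wald_linear_test(g, ph$trait, direction)
    call <- if (res$testable)
      as.character(classify_replication(res$p_one_sided, alpha_rep,
                                        alpha_dir))
    else NA_character_
    data.frame(snp_id = entry$snp_id, test_snp = snp,
               statistic = res$statistic,
               p_one_sided = res$p_one_sided,
               testable = res$testable, call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed versus expected replication for a tested catalog
#'
#' Joins test results with per-association analytic powers, removes
#' untestable associations from both sides, and produces the overall and
#' per-class expected/observed summaries with exact Poisson-binomial
#' prediction intervals.
#'
#' @param results Output of [test_curated_associations()].
#' @param powers Data frame: \code{snp_id}, \code{power}, optionally
#'   \code{class}.
#' @param exclude Character vector of \code{snp_id}s to exclude (e.g.
#'   associations with known conflicting evidence).
#' @return As [aggregate_by_class()].
#' @export
replication_summary <- function(results, powers, exclude = character()) {
  stopifnot(all(c("snp_id", "power") %in% names(powers)))
  merged <- merge(results[results$testable, , drop = FALSE], powers,
                  by = "snp_id")
  if (!"class" %in% names(merged)) merged$class <- "all"
  df <- data.frame(id = merged$snp_id, power = merged$power,
                   class = merged$class,
                   replicated = merged$call == "replicated")
  aggregate_by_class(df, exclude = exclude)
}
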