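# Synthetic catalogs, cohorts and surveys with the statistical structure
# the pipeline assumes: Hardy-Weinberg genotypes, logit-additive
# penetrance at a stated prevalence, misreported labels at stated rates,
# proxy SNPs at a target r2, and survey answers including uncertain and
# inconsistent responders. Everything is deterministic given the seed.

#' Simulation configuration
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_subjects Cohort size.
#' @param associations Data frame with columns \code{snp_id},
#'   \code{phenotype}, \code{raf}, \code{effect}, \code{trait_type}
#'   (\code{binary}/\code{quantitative}), \code{prevalence} (NA for
#'   quantitative), and optionally \code{class}.
#' @param e_case,e_control Misreport probabilities: a true case reports
#'   negative with probability \code{e_case}; a true control reports
#'   affirmative with probability \code{e_control}.
#' @param proxy_specs Optional data frame \code{snp_id}, \code{proxy_id},
#'   \code{target_r2}, \code{proxy_raf}: generate a proxy SNP in LD with
#'   the named SNP at the target r-squared.
#' @param p_uncertain,p_inconsistent Survey noise: probability that a
#'   responder answers only uncertainly, or answers the phenotype's two
#'   questions inconsistently.
#' @param interaction Optional numeric vector
#'   \code{c(intercept, risk, avail, interaction)} of log-odds
#'   coefficients for the reporting-bias generator.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed, n_subjects, associations,
                       e_case = 0.05, e_control = 0.05,
                       proxy_specs = NULL,
                       p_uncertain = 0.02, p_inconsistent = 0.01,
                       interaction = c(-2, 0.5, 0, 0)) {
  stopifnot(is.numeric(seed), n_subjects > 0,
            is.data.frame(associations),
            all(c("snp_id", "phenotype", "raf", "effect", "trait_type")
                %in% names(associations)),
            e_case >= 0, e_case < 0.5, e_control >= 0, e_control < 0.5,
            p_uncertain >= 0, p_uncertain <= 1,
            p_inconsistent >= 0, p_inconsistent <= 1)
  if (!"prevalence" %in% names(associations))
    associations$prevalence <- NA_real_
  if (!"class" %in% names(associations))
    associations$class <- "all"
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 associations = associations,
                 e_case = e_case, e_control = e_control,
                 proxy_specs = proxy_specs,
                 p_uncertain = p_uncertain,
                 p_inconsistent = p_inconsistent,
                 interaction = interaction),
            class = "sim_config")
}

# deterministic sub-stream seeds, kept within 32-bit integer range
substream_seed <- function(seed, label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) * 1009L +
    (as.integer(seed) %% 1000000L) * 31L
}

#' Generate a self-labelled synthetic association catalog
#'
#' Emits a catalog exercising every curation rule, together with a
#' matching LD table and platform manifest. Rows carry an
#' \code{expected_outcome} label (\code{retained}, \code{filtered},
#' \code{dedup_loser}, \code{ld_pruned}, \code{proxy}, \code{dropped},
#' \code{review}) stating the outcome the curation pipeline should
#' produce for them; the label column is ignored by the pipeline itself,
#' so the fixtures are self-verifying.
#'
#' @param config A [sim_config()]; its associations become the retained
#'   backbone entries.
#' @return List of data frames \code{catalog} (with
#'   \code{expected_outcome}), \code{ld}, \code{platform}, and
#'   \code{reference_freqs} (named vector).
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "catalog"))
  assoc <- config$associations
  n <- nrow(assoc)
  base <- data.frame(
    snp_id = assoc$snp_id, phenotype = assoc$phenotype,
    risk_allele = "A", other_allele = "G",
    raf = assoc$raf,
    effect = assoc$effect, trait_type = assoc$trait_type,
    p_value = 10^stats::runif(n, -12, -8),
    ancestry = "European",
    study_id = sprintf("PMID%05d", seq_len(n)),
    n_cases = 1000L + 100L * seq_len(n), n_controls = 2000L,
    single_snp = TRUE, includes_cohort = FALSE,
    expected_outcome = "retained")

  bad <- function(snp, outcome, ...) {
    row <- base[1, ]
    row$snp_id <- snp
    row$phenotype <- "synthetic_filter_trait"
    mods <- list(...)
    for (nm in names(mods)) row[[nm]] <- mods[[nm]]
    row$expected_outcome <- outcome
    row
  }
  extras <- rbind(
    bad("rsP_HIGH", "filtered", p_value = 1e-6),
    bad("rsNO_EFF", "filtered", effect = NA_real_),
    bad("rsHAPLO", "filtered", single_snp = FALSE),
    bad("rsASIAN", "filtered", ancestry = "East Asian"),
    bad("rsSELF", "filtered", includes_cohort = TRUE))

  # duplicate of the first backbone entry from a smaller study
  dup <- base[1, ]
  dup$study_id <- "PMID90001"
  dup$n_cases <- base$n_cases[1] - 500L
  dup$p_value <- base$p_value[1] / 10
  dup$expected_outcome <- "dedup_loser"

  # an LD partner of the first entry with a larger p (same study)
  ldpart <- base[1, ]
  ldpart$snp_id <- "rsLDPART"
  ldpart$p_value <- base$p_value[1] * 10
  ldpart$expected_outcome <- "ld_pruned"

  # off-platform entries: one with a usable proxy, one without
  prox <- bad("rsOFFPLAT", "proxy", p_value = 1e-9)
  noprox <- bad("rsNOPROXY", "dropped", p_value = 1e-9)

  # ambiguous alleles go to manual review
  ambig <- bad("rsAMBIG", "review", risk_allele = "A", other_allele = "T",
               p_value = 1e-9)

  catalog <- rbind(base, extras, dup, ldpart, prox, noprox, ambig)
  rownames(catalog) <- NULL

  ld <- data.frame(
    snp_a = c(base$snp_id[1], "rsOFFPLAT", "rsOFFPLAT", "rsNOPROXY"),
    snp_b = c("rsLDPART", "rsPROXY1", "rsPROXY2", "rsWEAK"),
    r2 = c(0.4, 0.8, 0.6, 0.3))
  if (n >= 2)  # an explicitly independent pair stays unpruned
    ld <- rbind(ld, data.frame(snp_a = base$snp_id[1],
                               snp_b = base$snp_id[2], r2 = 0.05))
  platform <- data.frame(
    snp_id = c(base$snp_id, "rsP_HIGH", "rsNO_EFF", "rsHAPLO", "rsASIAN",
               "rsSELF", "rsLDPART", "rsPROXY1", "rsPROXY2", "rsWEAK",
               "rsAMBIG"),
    call_rate = 0.999)
  ref <- stats::setNames(catalog$raf + stats::runif(nrow(catalog),
                                                    -0.02, 0.02),
                         catalog$snp_id)
  ref <- pmin(pmax(ref, 0.01), 0.99)
  list(catalog = catalog, ld = ld, platform = platform,
       reference_freqs = ref)
}

# haplotype frequencies for two biallelic loci at a target r2 (D > 0)
haplotype_freqs <- function(p_a, p_b, target_r2) {
  d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  d <- sqrt(target_r2 * p_a * (1 - p_a) * p_b * (1 - p_b))
  if (d > d_max + 1e-12) {
    r2_max <- d_max^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
    stop(sprintf(
      "target r2 %.3f unattainable for frequencies %.2f/%.2f (max %.3f)",
      target_r2, p_a, p_b, r2_max), call. = FALSE)
  }
  c(ab = p_a * p_b + d, aB = p_a * (1 - p_b) - d,
    Ab = (1 - p_a) * p_b - d, AB = (1 - p_a) * (1 - p_b) + d)
}

#' Generate a synthetic cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at each
#' association's risk-allele frequency. For binary traits, true disease
#' status follows the logit-additive penetrance model at the stated
#' prevalence, and reported status flips true cases to negative with
#' probability \code{e_case} and true controls to affirmative with
#' probability \code{e_control}. Quantitative traits are
#' \eqn{y = \beta g + \epsilon}, \eqn{\epsilon \sim N(0,1)}. Proxy SNPs
#' are generated from two-locus haplotype frequencies solved to hit the
#' target r-squared exactly in expectation. Covariates include age, sex,
#' smoking, five synthetic ancestry PCs, a results-available indicator
#' and a predicted risk score (generated under the configured
#' interaction model for the reporting-bias test).
#'
#' @param config A [sim_config()].
#' @return List: \code{genotypes} (subjects x SNPs integer matrix),
#'   \code{phenotypes} (data frame of true and reported status or trait
#'   per association), \code{covariates} data frame.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  n <- config$n_subjects
  assoc <- config$associations
  subj <- sprintf("S%06d", seq_len(n))

  geno <- sapply(assoc$raf, function(q) stats::rbinom(n, 2, q))
  colnames(geno) <- assoc$snp_id
  rownames(geno) <- subj

  phen <- list()
  for (i in seq_len(nrow(assoc))) {
    id <- assoc$snp_id[i]
    g <- geno[, i]
    if (assoc$trait_type[i] == "binary") {
      model <- genotype_distributions(assoc$raf[i], assoc$effect[i],
                                      assoc$prevalence[i])
      true <- stats::rbinom(n, 1, model$penetrances[g + 1]) == 1
      flip <- stats::runif(n)
      reported <- ifelse(true, flip >= config$e_case,
                         flip < config$e_control)
      phen[[id]] <- data.frame(subject_id = subj, association = id,
                               phenotype = assoc$phenotype[i],
                               true_status = true,
                               reported_status = reported,
                               trait = NA_real_)
    } else {
      y <- assoc$effect[i] * g + stats::rnorm(n)
      phen[[id]] <- data.frame(subject_id = subj, association = id,
                               phenotype = assoc$phenotype[i],
                               true_status = NA, reported_status = NA,
                               trait = y)
    }
  }
  phenotypes <- do.call(rbind, phen)
  rownames(phenotypes) <- NULL

  if (!is.null(config$proxy_specs)) {
    ps <- config$proxy_specs
    for (k in seq_len(nrow(ps))) {
      i <- match(ps$snp_id[k], assoc$snp_id)
      stopifnot(!is.na(i))
      p_a <- assoc$raf[i]
      p_b <- ps$proxy_raf[k]
      h <- haplotype_freqs(p_a, p_b, ps$target_r2[k])
      g_a <- geno[, i]
      # split each dosage into two latent haploid alleles, then draw the
      # proxy allele from the conditional haplotype distribution
      a1 <- ifelse(g_a == 2, 1L, ifelse(g_a == 0, 0L,
                                        stats::rbinom(n, 1, 0.5)))
      a2 <- g_a - a1
      p_b_given <- function(a) ifelse(a == 1, h["ab"] / p_a,
                                      h["Ab"] / (1 - p_a))
      b1 <- stats::rbinom(n, 1, p_b_given(a1))
      b2 <- stats::rbinom(n, 1, p_b_given(a2))
      geno <- cbind(geno, b1 + b2)
      colnames(geno)[ncol(geno)] <- ps$proxy_id[k]
    }
  }

  co <- config$interaction
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  covariates <- data.frame(
    subject_id = subj,
    age = pmin(pmax(round(stats::rnorm(n, 46, 15)), 20), 90),
    sex = ifelse(stats::runif(n) < 0.58, "male", "female"),
    smoker = stats::runif(n) < 0.4,
    pcs,
    results_available = stats::runif(n) < 0.5,
    predicted_risk = stats::rnorm(n))
  eta <- co[1] + co[2] * covariates$predicted_risk +
    co[3] * covariates$results_available +
    co[4] * covariates$predicted_risk * covariates$results_available
  covariates$report_bias_status <- stats::runif(n) < stats::plogis(eta)

  list(genotypes = geno, phenotypes = phenotypes,
       covariates = covariates)
}

#' Generate survey responses from reported status
#'
#' Each binary phenotype gets two questions probing the same diagnosis.
#' Responders answer both consistently with their reported status,
#' except a fraction \code{p_uncertain} who answer only uncertainly and
#' a fraction \code{p_inconsistent} who give one affirmative and one
#' negative answer.
#'
#' @param config A [sim_config()].
#' @param phenotypes \code{phenotypes} data frame from [gen_cohort()]
#'   (binary associations only are surveyed).
#' @return Data frame \code{subject_id}, \code{question_id},
#'   \code{answer}, \code{onset_age}, plus a \code{noise} label
#'   (\code{none}/\code{uncertain}/\code{inconsistent}) for
#'   self-verification.
#' @export
gen_surveys <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "surveys"))
  out <- list()
  bin <- phenotypes[!is.na(phenotypes$reported_status), , drop = FALSE]
  for (ph in unique(bin$phenotype)) {
    sub <- bin[bin$phenotype == ph, , drop = FALSE]
    sub <- sub[!duplicated(sub$subject_id), , drop = FALSE]
    m <- nrow(sub)
    q <- paste0("q_", ph, "_", 1:2)
    u <- stats::runif(m)
    noise <- ifelse(u < config$p_uncertain, "uncertain",
                    ifelse(u < config$p_uncertain + config$p_inconsistent,
                           "inconsistent", "none"))
    base_answer <- ifelse(sub$reported_status, "affirmative", "negative")
    a1 <- ifelse(noise == "uncertain", "uncertain",
                 ifelse(noise == "inconsistent", "affirmative",
                        base_answer))
    a2 <- ifelse(noise == "uncertain", "uncertain",
                 ifelse(noise == "inconsistent", "negative", base_answer))
    onset <- ifelse(sub$reported_status & noise == "none",
                    pmax(5, round(stats::rnorm(m, 35, 12))), NA)
    out[[ph]] <- data.frame(
      subject_id = rep(sub$subject_id, 2),
      question_id = rep(q, each = m),
      answer = c(a1, a2),
      onset_age = c(onset, onset),
      noise = rep(noise, 2))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical rejection rate of the trend test under the power model
#'
#' Simulates replicate case/control studies directly at the genotype-count
#' level: reported-case genotype counts are multinomial draws from the
#' misclassified case distribution and likewise for controls — exactly
#' the generative model the analytic power calculation assumes — and each
#' replicate is scored with the package's trend statistic.
#'
#' @inheritParams power_trend_test
#' @param n_reps Number of replicate studies.
#' @return List: \code{rejection_rate}, \code{z} (replicate statistics),
#'   \code{p_one_sided}.
#' @export
simulate_trend_replicates <- function(n_cases, n_controls, raf,
                                      or_published, prevalence,
                                      alpha = 0.05,
                                      sided = c("one", "two"),
                                      e_case = 0.05,
                                      e_control = min(prevalence, 0.10),
                                      n_reps = 1000) {
  sided <- match.arg(sided)
  model <- genotype_distributions(raf, or_published, prevalence)
  model <- apply_misclassification(model, e_case, e_control)
  cases <- t(stats::rmultinom(n_reps, n_cases, model$case_dist))
  controls <- t(stats::rmultinom(n_reps, n_controls, model$control_dist))
  z <- trend_z_from_counts(cases, controls)
  direction <- if (or_published >= 1) "+" else "-"
  p <- one_sided_p(z, direction)
  reject <- if (sided == "one") p < alpha
            else abs(z) > stats::qnorm(1 - alpha / 2)
  list(rejection_rate = mean(reject, na.rm = TRUE), z = z,
       p_one_sided = p)
}

#' Calibration of the replication prediction interval
#'
#' For a table of associations, computes each association's analytic
#' power and the 95 percent Poisson-binomial prediction interval for the
#' total replication count, then simulates whole-study replicates (every
#' association redrawn from its own generative model and re-tested) and
#' reports how often the observed count falls inside the interval.
#'
#' @param inputs Data frame: \code{n_cases}, \code{n_controls},
#'   \code{raf}, \code{or_published}, \code{prevalence}, optionally
#'   \code{e_case}, \code{e_control}.
#' @param n_reps Number of whole-study replicates.
#' @param alpha Replication threshold (one-sided), default 0.05.
#' @param coverage Interval coverage, default 0.95.
#' @return List: \code{powers}, \code{interval}, \code{expected},
#'   \code{observed} (vector over replicates), \code{inside_rate}.
#' @export
calibrate_prediction_interval <- function(inputs, n_reps = 200,
                                          alpha = 0.05, coverage = 0.95) {
  n <- nrow(inputs)
  ec <- if ("e_case" %in% names(inputs)) inputs$e_case else rep(0.05, n)
  eo <- if ("e_control" %in% names(inputs)) inputs$e_control
        else pmin(inputs$prevalence, 0.10)
  powers <- numeric(n)
  success <- matrix(FALSE, n_reps, n)
  for (i in seq_len(n)) {
    powers[i] <- power_trend_test(
      inputs$n_cases[i], inputs$n_controls[i], inputs$raf[i],
      inputs$or_published[i], inputs$prevalence[i],
      alpha = alpha, sided = "one", e_case = ec[i], e_control = eo[i])$power
    sim <- simulate_trend_replicates(
      inputs$n_cases[i], inputs$n_controls[i], inputs$raf[i],
      inputs$or_published[i], inputs$prevalence[i],
      alpha = alpha, sided = "one", e_case = ec[i], e_control = eo[i],
      n_reps = n_reps)
    success[, i] <- !is.na(sim$p_one_sided) & sim$p_one_sided < alpha
  }
  interval <- prediction_interval(poisson_binomial_dp(powers), coverage)
  observed <- rowSums(success)
  list(powers = powers, interval = interval, expected = sum(powers),
       observed = observed,
       inside_rate = mean(observed >= interval[1] &
                            observed <= interval[2]))
}
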