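# Per-association replication tests. Genotypes are risk-allele dosages
# (0/1/2), oriented to the published risk allele, so the published
# direction is "+" for OR > 1 or beta > 0 and "-" otherwise.

#' Trend statistic from a 2x3 genotype table
#'
#' Core of the Cochran-Armitage trend test (equivalently the score test
#' for logistic regression of status on dosage with no covariates).
#' Vectorized over rows so that simulation studies can score many
#' replicate tables at once.
#'
#' @param case_counts,control_counts Matrix (replicates x 3) or length-3
#'   vector of genotype counts over dosages 0, 1, 2.
#' @return Signed z statistic(s); positive when cases carry more risk
#'   alleles than controls. \code{NA} where the table is degenerate
#'   (either group empty, or all subjects share one genotype).
#' @export
trend_z_from_counts <- function(case_counts, control_counts) {
  if (is.null(dim(case_counts))) case_counts <- rbind(case_counts)
  if (is.null(dim(control_counts))) control_counts <- rbind(control_counts)
  stopifnot(ncol(case_counts) == 3, ncol(control_counts) == 3)
  x <- 0:2
  r <- rowSums(case_counts)
  s <- rowSums(control_counts)
  n_g <- case_counts + control_counts
  n <- r + s
  u <- case_counts %*% x - r * (n_g %*% x) / n
  v <- (r * s / n) * ((n_g %*% x^2) / n - ((n_g %*% x) / n)^2)
  z <- as.vector(u) / sqrt(as.vector(v))
  z[r == 0 | s == 0 | as.vector(v) <= 0] <- NA_real_
  z
}

#' One-sided Cochran-Armitage trend test
#'
#' Score test for logistic regression of a binary phenotype on risk-allele
#' dosage, with the p-value taken one-sided in the published direction of
#' effect.
#'
#' @param genotypes Integer dosages in \{0, 1, 2\}; \code{NA} allowed
#'   (complete-case).
#' @param status Binary phenotype (logical, or 0/1) aligned with
#'   \code{genotypes}.
#' @param direction \code{"+"} if the published effect increases risk with
#'   dosage, \code{"-"} otherwise.
#' @return A list of class \code{assoc_test}: \code{statistic} (signed z),
#'   \code{p_one_sided}, \code{n_cases}, \code{n_controls},
#'   \code{testable}, and \code{reason} when untestable.
#' @export
trend_score_test <- function(genotypes, status, direction = c("+", "-")) {
  direction <- match.arg(direction)
  ok <- !is.na(genotypes) & !is.na(status)
  g <- genotypes[ok]
  y <- as.logical(status[ok])
  stopifnot(all(g %in% 0:2))
  case_counts <- tabulate(g[y] + 1L, 3L)
  control_counts <- tabulate(g[!y] + 1L, 3L)
  z <- trend_z_from_counts(case_counts, control_counts)
  out <- list(statistic = z,
              p_one_sided = NA_real_,
              n_cases = sum(y), n_controls = sum(!y),
              direction_published = direction,
              testable = !is.na(z), reason = NA_character_)
  if (is.na(z)) {
    out$reason <- if (sum(y) == 0 || sum(!y) == 0) "empty_group"
                  else "constant_genotype"
  } else {
    out$p_one_sided <- one_sided_p(z, direction)
  }
  class(out) <- "assoc_test"
  out
}

one_sided_p <- function(z, direction) {
  if (direction == "+") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z)
}

#' One-sided Wald test for a quantitative trait
#'
#' Ordinary least-squares regression of the trait on risk-allele dosage;
#' the Wald z is the slope over its standard error, with the p-value
#' one-sided in the published direction.
#'
#' @inheritParams trend_score_test
#' @param trait Numeric phenotype.
#' @return An \code{assoc_test} list with \code{effect_estimate} (slope),
#'   \code{se}, \code{statistic}, \code{p_one_sided}, \code{ci95}, and
#'   \code{n}.
#' @export
wald_linear_test <- function(genotypes, trait, direction = c("+", "-")) {
  direction <- match.arg(direction)
  ok <- !is.na(genotypes) & !is.na(trait)
  g <- genotypes[ok]
  y <- trait[ok]
  stopifnot(all(g %in% 0:2))
  out <- list(effect_estimate = NA_real_, se = NA_real_,
              statistic = NA_real_, p_one_sided = NA_real_,
              ci95 = c(NA_real_, NA_real_), n = length(y),
              direction_published = direction,
              testable = FALSE, reason = NA_character_)
  class(out) <- "assoc_test"
  if (length(y) < 3 || stats::var(g) == 0 || stats::var(y) == 0) {
    out$reason <- "degenerate_design"
    return(out)
  }
  fit <- stats::lm(y ~ g)
  sm <- summary(fit)$coefficients
  b <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  z <- if (se > 0) b / se else sign(b) * Inf
  out$effect_estimate <- b
  out$se <- se
  out$statistic <- z
  out$p_one_sided <- max(one_sided_p(z, direction), .Machine$double.xmin)
  out$ci95 <- b + c(-1, 1) * stats::qnorm(0.975) * se
  out$testable <- TRUE
  out
}

#' Per-allele odds ratio with 95 percent confidence interval
#'
#' Logistic regression of case/control status on dosage; Wald interval
#' \eqn{\exp(\hat\beta \pm 1.96\,SE)}. Quasi-complete separation is
#' reported, not corrected: the estimate is flagged and the interval set
#' to (0, Inf).
#'
#' @inheritParams trend_score_test
#' @param published_or Optional published odds ratio; when given, the
#'   result records whether the interval contains it.
#' @return A list: \code{or}, \code{log_or}, \code{se}, \code{ci95} (OR
#'   scale), \code{separation}, and \code{contains_published} (NA when
#'   \code{published_or} is missing).
#' @export
or_with_ci <- function(genotypes, status, published_or = NULL) {
  ok <- !is.na(genotypes) & !is.na(status)
  g <- genotypes[ok]
  y <- as.logical(status[ok])
  fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
  b <- stats::coef(fit)[["g"]]
  se <- sqrt(stats::vcov(fit)["g", "g"])
  separation <- !fit$converged || abs(b) > 15 || se > 100
  ci <- if (separation) c(0, Inf) else exp(b + c(-1, 1) * 1.96 * se)
  list(or = exp(b), log_or = b, se = se, ci95 = ci,
       separation = separation,
       contains_published = if (is.null(published_or)) NA
                            else published_or >= ci[1] && published_or <= ci[2])
}

#' Classify a replication attempt
#'
#' A one-sided p below \code{alpha_rep} counts as a replication; below
#' \code{alpha_dir} (but not \code{alpha_rep}) the test at least agreed
#' with the published direction of effect; otherwise the association did
#' not replicate.
#'
#' @param p_one_sided One-sided p-value(s) in the published direction.
#' @param alpha_rep Replication threshold, default 0.05.
#' @param alpha_dir Directionality threshold, default 0.5.
#' @return Factor with levels \code{replicated}, \code{directional_only},
#'   \code{not_replicated}.
#' @export
classify_replication <- function(p_one_sided, alpha_rep = 0.05,
                                 alpha_dir = 0.5) {
  stopifnot(alpha_rep < alpha_dir)
  out <- ifelse(p_one_sided < alpha_rep, "replicated",
                ifelse(p_one_sided < alpha_dir, "directional_only",
                       "not_replicated"))
  factor(out, levels = c("replicated", "directional_only", "not_replicated"))
}

#' Interaction of predicted risk with results availability
#'
#' Tests whether seeing one's genetic results changes the relationship
#' between predicted risk and the phenotype a participant subsequently
#' reports (a reporting-bias check). Logistic regression of reported
#' phenotype on predicted risk, a results-available indicator, their
#' interaction, and age, sex and five ancestry principal components; the
#' Wald p-value of the interaction term is returned.
#'
#' @param status Reported binary phenotype.
#' @param predicted_risk Numeric predicted risk per subject.
#' @param results_available Logical indicator that results were visible
#'   before the survey answer.
#' @param covariates Data frame with columns \code{age}, \code{sex}, and
#'   \code{pc1}..\code{pc5}.
#' @return A list: \code{p_interaction}, \code{estimate} (interaction
#'   log-odds), \code{se}.
#' @export
interaction_risk_report_test <- function(status, predicted_risk,
                                         results_available, covariates) {
  stopifnot(is.data.frame(covariates),
            all(c("age", "sex", paste0("pc", 1:5)) %in% names(covariates)))
  if (length(unique(results_available)) < 2)
    stop("interaction inestimable: results_available is constant",
         call. = FALSE)
  df <- data.frame(y = as.logical(status), risk = predicted_risk,
                   avail = as.logical(results_available),
                   covariates[c("age", "sex", paste0("pc", 1:5))])
  fit <- stats::glm(
    y ~ risk * avail + age + sex + pc1 + pc2 + pc3 + pc4 + pc5,
    family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  row <- grep("^risk:", rownames(sm))
  list(p_interaction = sm[row, "Pr(>|z|)"],
       estimate = sm[row, "Estimate"], se = sm[row, "Std. Error"])
}

#' @export
print.assoc_test <- function(x, ...) {
  if (!x$testable) {
    cat("untestable association (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("z = %.3f, one-sided p = %.3g (direction %s)\n",
                x$statistic, x$p_one_sided, x$direction_published))
  }
  invisible(x)
}
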