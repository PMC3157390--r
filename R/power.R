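#' Genotype distributions implied by a per-allele odds ratio
#'
#' Builds the case/control genotype distributions used by the trend-test
#' power model. Genotype frequencies follow Hardy-Weinberg equilibrium at
#' the risk-allele frequency; penetrance follows a logit-additive
#' (multiplicative-odds) model, \eqn{odds(g) = odds_0 \cdot OR^g} for
#' \eqn{g \in \{0,1,2\}} copies of the risk allele, with the baseline odds
#' \eqn{odds_0} solved numerically so the population prevalence
#' \eqn{\sum_g f(g)\,pen(g)} matches \code{prevalence}.
#'
#' @param raf Risk-allele frequency, in (0, 1).
#' @param or_published Per-allele odds ratio, positive.
#' @param prevalence Population disease prevalence, in (0, 1).
#' @return An object of class \code{genotype_model}: a list with
#'   \code{genotype_freqs}, \code{penetrances}, \code{case_dist} and
#'   \code{control_dist}, each a length-3 vector over dosages 0, 1, 2.
#' @examples
#' m <- genotype_distributions(raf = 0.3, or_published = 1.3, prevalence = 0.01)
#' sum(m$genotype_freqs * m$penetrances)  # = 0.01
#' @export
genotype_distributions <- function(raf, or_published, prevalence) {
  stopifnot(raf > 0, raf < 1, or_published > 0,
            prevalence > 0, prevalence < 1)
  g <- 0:2
  f <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  log_or <- log(or_published)
  # root of prevalence constraint in the baseline log-odds
  fn <- function(b0) sum(f * stats::plogis(b0 + g * log_or)) - prevalence
  root <- tryCatch(
    stats::uniroot(fn, interval = c(-700, 700), tol = 1e-12),
    error = function(e) stop("no baseline odds solves the prevalence ",
                             "constraint for these parameters", call. = FALSE))
  pen <- stats::plogis(root$root + g * log_or)
  case_dist <- f * pen / sum(f * pen)
  control_dist <- f * (1 - pen) / sum(f * (1 - pen))
  structure(
    list(genotype_freqs = f, penetrances = pen,
         case_dist = case_dist, control_dist = control_dist),
    class = "genotype_model")
}

#' Mix case and control genotype distributions under misclassification
#'
#' Models phenotyping error as label mixing: a proportion \code{e_case} of
#' reported cases are in truth controls, and \code{e_control} of reported
#' controls are (or will become) cases. The observed genotype distribution
#' in each reported group is the corresponding convex combination of the
#' true group distributions.
#'
#' @param model A \code{genotype_model} from [genotype_distributions()].
#' @param e_case Proportion of reported cases that are truly controls,
#'   in \[0, 0.5).
#' @param e_control Proportion of reported controls that are truly cases,
#'   in \[0, 0.5).
#' @return A \code{genotype_model} with mixed \code{case_dist} and
#'   \code{control_dist}.
#' @export
apply_misclassification <- function(model, e_case, e_control) {
  stopifnot(inherits(model, "genotype_model"),
            e_case >= 0, e_case < 0.5, e_control >= 0, e_control < 0.5)
  obs_case <- (1 - e_case) * model$case_dist + e_case * model$control_dist
  obs_control <- (1 - e_control) * model$control_dist +
    e_control * model$case_dist
  model$case_dist <- obs_case
  model$control_dist <- obs_control
  model
}

#' Effective sample size under proxy-SNP testing
#'
#' When an association is tested through a proxy SNP in incomplete LD with
#' the reported SNP, the information available is attenuated; the sample
#' size entering the power calculation is scaled by the pairwise r-squared.
#'
#' @param n Sample size, positive.
#' @param proxy_r2 Squared correlation between proxy and reported SNP,
#'   in (0, 1\].
#' @return \code{n * proxy_r2} (not rounded).
#' @export
effective_sample_size <- function(n, proxy_r2) {
  stopifnot(all(n > 0), all(proxy_r2 > 0), all(proxy_r2 <= 1))
  n * proxy_r2
}

#' Winner's-curse adjustment of a log odds ratio
#'
#' Discovery studies tend to overestimate effect sizes (winner's curse).
#' This helper applies a fixed relative inflation on the log-odds scale:
#' \code{inflate} maps a true log OR to the expected reported one,
#' \code{deflate} inverts that map to recover a true log OR from a
#' reported one.
#'
#' @param log_or Log odds ratio(s).
#' @param inflation Relative inflation of the log OR, nonnegative
#'   (0.15 for 15 percent).
#' @param mode \code{"deflate"} (default) or \code{"inflate"}.
#' @return Adjusted log odds ratio(s).
#' @examples
#' exp(adjust_winners_curse(log(1.25), 0.15, "inflate"))  # about 1.29
#' @export
adjust_winners_curse <- function(log_or, inflation,
                                 mode = c("deflate", "inflate")) {
  stopifnot(inflation >= 0)
  mode <- match.arg(mode)
  if (mode == "inflate") log_or * (1 + inflation) else log_or / (1 + inflation)
}

#' Analytic power of the misclassification-adjusted trend test
#'
#' Computes normal-approximation power of the Cochran-Armitage trend test
#' (score test for logistic regression on dosage) for a case/control study
#' of a published per-allele odds ratio, allowing for phenotype
#' misclassification, proxy-SNP attenuation and winner's-curse deflation
#' of the published effect.
#'
#' The computation: (1) optionally deflate the published log OR by the
#' winner's-curse factor; (2) build case/control genotype distributions
#' from Hardy-Weinberg frequencies and the logit-additive penetrance model
#' at the given prevalence; (3) mix the distributions according to the
#' misclassification proportions; (4) scale both group sizes by
#' \code{proxy_r2}; (5) evaluate
#' \eqn{power = \Phi(\Delta/\sigma_1 - z_{crit}\,\sigma_0/\sigma_1)}
#' where \eqn{\Delta} is the difference in mean dosage between observed
#' cases and controls, \eqn{\sigma_0} and \eqn{\sigma_1} are its standard
#' errors under the null (pooled dosage variance) and the alternative, and
#' \eqn{z_{crit}} is the standard-normal critical value at \code{alpha}
#' (halved for a two-sided test). Dosage variances are taken from the
#' mixed genotype distributions themselves, so no within-group
#' Hardy-Weinberg assumption is made.
#'
#' @param n_cases,n_controls Reported group sizes, positive.
#' @param raf Risk-allele frequency in controls, in (0, 1).
#' @param or_published Published per-allele odds ratio, positive.
#' @param prevalence Disease prevalence, in (0, 1).
#' @param alpha Significance threshold.
#' @param sided \code{"one"} (default, in the published direction) or
#'   \code{"two"}.
#' @param e_case Case misclassification proportion; default 0.05.
#' @param e_control Control misclassification proportion; default
#'   \code{min(prevalence, 0.10)}.
#' @param proxy_r2 Proxy r-squared; 1 when the reported SNP is tested.
#' @param inflation Winner's-curse log-OR inflation assumed in the
#'   published estimate; the model deflates by this factor. Default 0.
#' @return A list of class \code{power_result}: \code{power},
#'   \code{noncentrality} (the mean of the standardized statistic under
#'   the alternative), \code{effective_n_cases},
#'   \code{effective_n_controls}.
#' @examples
#' power_trend_test(3000, 3000, raf = 0.3, or_published = 1.3,
#'                  prevalence = 0.05, alpha = 1e-7, sided = "two",
#'                  e_case = 0.05, e_control = 0.05)$power
#' @export
power_trend_test <- function(n_cases, n_controls, raf, or_published,
                             prevalence, alpha = 0.05,
                             sided = c("one", "two"),
                             e_case = 0.05,
                             e_control = min(prevalence, 0.10),
                             proxy_r2 = 1, inflation = 0) {
  sided <- match.arg(sided)
  stopifnot(n_cases > 0, n_controls > 0, alpha > 0, alpha < 1,
            proxy_r2 > 0, proxy_r2 <= 1, inflation >= 0)
  or_true <- exp(adjust_winners_curse(log(or_published), inflation, "deflate"))
  model <- genotype_distributions(raf, or_true, prevalence)
  model <- apply_misclassification(model, e_case, e_control)

  g <- 0:2
  r <- effective_sample_size(n_cases, proxy_r2)
  s <- effective_sample_size(n_controls, proxy_r2)
  mu_case <- sum(g * model$case_dist)
  mu_control <- sum(g * model$control_dist)
  v_case <- sum(g^2 * model$case_dist) - mu_case^2
  v_control <- sum(g^2 * model$control_dist) - mu_control^2
  # pooled distribution over reported labels gives the null variance
  w <- r / (r + s)
  pooled <- w * model$case_dist + (1 - w) * model$control_dist
  mu_pool <- sum(g * pooled)
  v_pool <- sum(g^2 * pooled) - mu_pool^2

  delta <- mu_case - mu_control
  sd0 <- sqrt(v_pool * (1 / r + 1 / s))
  sd1 <- sqrt(v_case / r + v_control / s)
  z_crit <- stats::qnorm(1 - if (sided == "two") alpha / 2 else alpha)
  ncp <- delta / sd1
  power <- stats::pnorm(ncp - z_crit * sd0 / sd1)
  if (sided == "two")  # opposite tail, negligible except near the null
    power <- power + stats::pnorm(-ncp - z_crit * sd0 / sd1)
  structure(
    list(power = power, noncentrality = ncp,
         effective_n_cases = r, effective_n_controls = s),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("trend-test power: %.4f (ncp %.3f, effective n %.1f/%.1f)\n",
              x$power, x$noncentrality,
              x$effective_n_cases, x$effective_n_controls))
  invisible(x)
}
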