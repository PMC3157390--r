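#' Exact distribution of the number of successful replications
#'
#' Each attempted replication is modelled as an independent Bernoulli
#' event with success probability equal to its estimated power. The
#' distribution of the total number of successes (a Poisson-binomial
#' distribution) is computed exactly by the dynamic-programming
#' recurrence \eqn{f_i(k) = f_{i-1}(k)(1-p_i) + f_{i-1}(k-1)\,p_i},
#' starting from a point mass at zero.
#'
#' @param powers Numeric vector of success probabilities in \[0, 1\];
#'   may be empty (degenerate distribution at 0).
#' @return Numeric vector of length \code{length(powers) + 1}: the
#'   probability mass function over 0..n successes.
#' @examples
#' poisson_binomial_dp(c(0.5, 0.5, 0.5))  # binomial(3, 0.5) masses
#' @export
poisson_binomial_dp <- function(powers) {
  if (anyNA(powers) || any(powers < 0 | powers > 1))
    stop("powers must be probabilities in [0, 1]", call. = FALSE)
  pmf <- 1
  for (p in powers)
    pmf <- c(pmf, 0) * (1 - p) + c(0, pmf) * p
  pmf
}

#' Prediction interval for a replication count
#'
#' Given the exact probability mass function of the number of successes,
#' returns the interval \[L, U\] where L is the largest integer such that
#' P(X < L) is at most (1 - coverage)/2 and U the smallest integer such
#' that P(X > U) is at most (1 - coverage)/2.
#'
#' @param pmf Probability mass function over 0..n (e.g. from
#'   [poisson_binomial_dp()]).
#' @param coverage Nominal coverage, default 0.95.
#' @return Integer vector \code{c(L, U)}.
#' @examples
#' prediction_interval(dbinom(0:20, 20, 0.5))  # c(6, 14)
#' @export
prediction_interval <- function(pmf, coverage = 0.95) {
  stopifnot(length(pmf) >= 1, all(pmf >= -1e-12),
            abs(sum(pmf) - 1) < 1e-8, coverage > 0, coverage < 1)
  tail <- (1 - coverage) / 2
  n <- length(pmf) - 1
  cdf <- cumsum(pmf)
  # P(X < l) = cdf[l] in R's 1-based indexing (cdf[l] = P(X <= l-1))
  lower_tail <- c(0, cdf[seq_len(n)])
  l <- max(which(lower_tail <= tail + 1e-12)) - 1L
  upper_tail <- 1 - cdf
  u <- min(which(upper_tail <= tail + 1e-12)) - 1L
  c(l, u)
}

#' Expected versus observed replication summary
#'
#' Combines per-association replication powers with the observed number
#' of successes: the expected count is the sum of the powers, the
#' prediction interval comes from the exact Poisson-binomial
#' distribution, and both the observed count and the interval are
#' reported as ratios to the expected count.
#'
#' @param powers Numeric vector of per-association powers in \[0, 1\].
#' @param observed Observed number of successes (a count), or a logical
#'   vector of per-association outcomes.
#' @param coverage Interval coverage, default 0.95.
#' @return A one-row data frame: \code{attempts}, \code{expected},
#'   \code{observed}, \code{ratio}, \code{count_lo}, \code{count_hi},
#'   \code{ratio_lo}, \code{ratio_hi}, \code{inside_interval}.
#' @export
success_ratio_summary <- function(powers, observed, coverage = 0.95) {
  if (is.logical(observed)) observed <- sum(observed)
  stopifnot(length(observed) == 1, observed >= 0,
            observed <= length(powers))
  expected <- sum(powers)
  pmf <- poisson_binomial_dp(powers)
  ci <- prediction_interval(pmf, coverage)
  ratio <- if (expected > 0) observed / expected else NA_real_
  data.frame(
    attempts = length(powers),
    expected = expected,
    observed = observed,
    ratio = ratio,
    count_lo = ci[1], count_hi = ci[2],
    ratio_lo = if (expected > 0) ci[1] / expected else NA_real_,
    ratio_hi = if (expected > 0) ci[2] / expected else NA_real_,
    inside_interval = observed >= ci[1] && observed <= ci[2])
}

#' Replication summaries by disease class
#'
#' Runs [success_ratio_summary()] for each disease class and for the
#' overall set, after removing an optional exclusion list (for instance
#' associations with known conflicting evidence whose power would be
#' overestimated).
#'
#' @param powers Data frame with columns \code{id}, \code{power},
#'   \code{class}, and logical \code{replicated}.
#' @param exclude Character vector of ids to drop from all summaries.
#' @param coverage Interval coverage, default 0.95.
#' @return A data frame with one row per class plus a final
#'   \code{"overall"} row, with the columns of
#'   [success_ratio_summary()] prefixed by \code{class}.
#' @export
aggregate_by_class <- function(powers, exclude = character(),
                               coverage = 0.95) {
  stopifnot(is.data.frame(powers),
            all(c("id", "power", "class", "replicated") %in% names(powers)))
  if (any(is.na(powers$class)))
    stop("associations without a class: ",
         paste(powers$id[is.na(powers$class)], collapse = ", "),
         call. = FALSE)
  keep <- !(powers$id %in% exclude)
  powers <- powers[keep, , drop = FALSE]
  one <- function(df, label) {
    cbind(class = label,
          success_ratio_summary(df$power, sum(df$replicated), coverage))
  }
  per_class <- lapply(split(powers, powers$class),
                      function(df) one(df, df$class[1]))
  out <- do.call(rbind, c(per_class, list(one(powers, "overall"))))
  rownames(out) <- NULL
  out
}

#' Expected directionality among non-replicated associations
#'
#' For associations that did not replicate at the replication threshold,
#' recomputes each association's success probability with the one-sided
#' threshold raised to \code{alpha_dir} (0.5 by default, i.e. the chance
#' of observing the published direction of effect at all) and summarizes
#' expected versus observed directional agreement with the same
#' Poisson-binomial machinery.
#'
#' @param inputs Data frame of power-model inputs for the non-replicated
#'   associations: columns \code{n_cases}, \code{n_controls}, \code{raf},
#'   \code{or_published}, \code{prevalence}, and optionally
#'   \code{e_case}, \code{e_control}, \code{proxy_r2}.
#' @param observed_directional Observed count (or logical vector) of
#'   non-replicated associations whose one-sided p fell below
#'   \code{alpha_dir}.
#' @param alpha_dir Directionality threshold, default 0.5.
#' @return As [success_ratio_summary()], with an extra attribute
#'   \code{"powers"} holding the recomputed per-association powers.
#' @export
expected_directionality <- function(inputs, observed_directional,
                                    alpha_dir = 0.5) {
  stopifnot(is.data.frame(inputs),
            all(c("n_cases", "n_controls", "raf", "or_published",
                  "prevalence") %in% names(inputs)))
  n <- nrow(inputs)
  ec <- if ("e_case" %in% names(inputs)) inputs$e_case else rep(0.05, n)
  eo <- if ("e_control" %in% names(inputs)) inputs$e_control
        else pmin(inputs$prevalence, 0.10)
  r2 <- if ("proxy_r2" %in% names(inputs)) inputs$proxy_r2 else rep(1, n)
  p_dir <- vapply(seq_len(n), function(i) {
    power_trend_test(inputs$n_cases[i], inputs$n_controls[i],
                     inputs$raf[i], inputs$or_published[i],
                     inputs$prevalence[i], alpha = alpha_dir,
                     sided = "one", e_case = ec[i], e_control = eo[i],
                     proxy_r2 = r2[i])$power
  }, numeric(1))
  out <- success_ratio_summary(p_dir, observed_directional)
  attr(out, "powers") <- p_dir
  out
}
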