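---
title: "Replication expectations for published genetic associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication expectations for published genetic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replix)
```

## The problem

A cohort with genome-wide genotypes and self-reported phenotypes can try
to replicate published SNP-trait associations wholesale. A raw
replication rate ("we confirmed 37% of published hits") is
uninterpretable on its own, because power varies enormously across
associations: a failure to replicate a weak effect in a small phenotype
group carries little information, while a failure at 99% power is a
genuine anomaly. `replix` implements the complete accounting needed to
interpret such an exercise:

1. **Curation** of a GWAS-catalog-style list into a non-redundant,
   testable set of associations.
2. **Phenotyping** from self-reported survey answers, with principled
   exclusions.
3. **Association testing**, one-sided in the published direction.
4. **Power**, per association, under a model that includes phenotype
   misclassification, proxy-SNP attenuation and winner's-curse
   correction.
5. **Expectation**: the exact distribution of the number of successful
   replications implied by those powers, with 95% prediction
   intervals, so the observed count can be judged against what the
   published effect sizes actually predict.
6. A **synthetic-data generator** so every stage can be exercised and
   calibrated without access to any real cohort.

## Curation rules

Starting from a table of published associations (SNP, phenotype, risk
allele, risk-allele frequency, OR or beta, p-value, ancestry, study,
case/control counts), `curate_catalog()` applies, in order:

* **Eligibility**: discovery p ≤ 1e-7 (limits false positives in the
  source list), a reported effect size, single-SNP (not haplotype)
  associations, European discovery ancestry, and no overlap between the
  discovery study and the replication cohort.
* **Deduplication**: one entry per (SNP, phenotype), keeping the study
  with the most cases. The tie-break (smaller p, then study id) is a
  package choice made for determinism.
* **LD pruning**: within a phenotype, SNPs with pairwise r² ≥ 0.1 are
  grouped into connected components and one association is kept per
  component — within one study the smallest p, across studies the
  largest case count. Connected components (rather than greedy pairwise
  pruning) make the result independent of input order; missing LD pairs
  count as r² = 0, which is conservative in that it never merges
  blocks. Pruning is per-phenotype, since associations are
  phenotype-specific.
* **Proxy selection**: the reported SNP is tested if it is on the
  platform with call rate ≥ 99%; otherwise the highest-r² proxy with
  r² ≥ 0.5 substitutes (highest r² maximizes retained information);
  otherwise the association is dropped with a recorded reason.
* **Strand checks**: reported risk-allele frequency is compared with a
  reference-panel frequency; both < 0.35 or both > 0.65 counts as a
  match (values exactly at the band edge do not). Unambiguous SNPs with
  matching frequencies are confirmed; ambiguous (A/T, C/G) SNPs,
  missing reference data, and mismatches are routed to a manual-review
  table rather than resolved automatically; entries the analyst marks
  unresolvable are removed from testing.

Curation is idempotent: running it on its own output changes nothing.

## Phenotyping rules

`assign_case_control()` maps survey answers to status per phenotype: at
least one affirmative answer (and no negative) makes a case; at least
one negative (and no affirmative) a control; a mixture within one
phenotype's question set is excluded as inconsistent; only
uncertain/declined answers, or silence, excludes. Inconsistency is
judged within a single phenotype's questions only.

Restrictions then move non-conforming subjects to excluded:
onset-age windows for e.g. juvenile-onset conditions (cases only), sex
and smoking matching (both groups), and — for late-onset diseases — a
control age floor. `restrict_controls_by_age()` keeps a control of age
*a* only if the residual lifetime risk
$(F_\infty - F(a))/(1 - F(a)) \le 0.10$, i.e. at least 90% of retained
controls are expected never to develop the disease. Incidence curves
are piecewise-linear between tabulated ages (smooth, reproducible
thresholding); attained age at survey is used.

## Tests

Binary traits use the Cochran-Armitage trend test (the score test for
logistic regression of status on 0/1/2 risk-allele dosage, no
covariates), quantitative traits the Wald test from ordinary least
squares. All p-values are one-sided in the published direction, from
the signed normal statistic. p < 0.05 counts as replication;
0.05 ≤ p < 0.5 as directional agreement only. Missing genotypes are
dropped per association; monomorphic or single-group designs are
flagged untestable and excluded from both the observed and expected
sides of the accounting. A separate reporting-bias check
(`interaction_risk_report_test()`) regresses reported phenotype on
predicted risk, a results-available indicator, their interaction, age,
sex and five ancestry PCs, and tests the interaction.

## The power model

`power_trend_test()` computes analytic power for the trend test from
the published per-allele OR:

* Genotypes follow Hardy-Weinberg equilibrium at the control
  risk-allele frequency; penetrance is logit-additive,
  $\mathrm{odds}(g) = \mathrm{odds}_0 \cdot OR^g$, with
  $\mathrm{odds}_0$ solved so the population prevalence matches. The
  per-allele OR admits several genetic models; the multiplicative-odds
  form matches the logistic regression actually used for testing.
* **Misclassification** mixes the group distributions: a fraction
  `e_case` (default 5%) of reported cases draw their genotype from the
  control distribution, and `e_control` (default min(prevalence, 10%))
  of reported controls from the case distribution — some "controls"
  are simply cases who have not yet developed or reported the disease.
* **Proxy attenuation** scales both group sizes by r²; non-integer
  effective sizes are used as-is.
* **Winner's curse**: discovery effect sizes are biased away from the
  null, modelled as a fixed relative inflation of the log OR
  (`adjust_winners_curse()`); 15% inflation maps a true OR of 1.25 to
  a reported 1.3 and 1.41 to 1.5. Power can deflate the published
  log OR by this factor before computing.
* Power is the normal approximation
  $\Phi(\Delta/\sigma_1 - z_{crit}\,\sigma_0/\sigma_1)$, where
  $\Delta$ is the difference in mean dosage between the observed
  (mixed) case and control distributions, $\sigma_0$ the null standard
  error from the pooled dosage variance, and $\sigma_1$ the standard
  error under the alternative. The dosage variance is taken from the
  mixture distributions themselves rather than from allele counts
  under a within-group Hardy-Weinberg assumption: the misclassified
  mixtures are not Hardy-Weinberg distributed, and the trend test
  operates on dosages. The two choices coincide asymptotically for
  unmixed groups. No continuity or small-sample correction is applied;
  at OR = 1 power equals α exactly.

```{r power}
# 3,000 cases and controls, RAF 0.30, OR 1.3, 5% symmetric phenotyping
# error, two-sided genome-wide threshold
power_trend_test(3000, 3000, raf = 0.30, or_published = 1.3,
                 prevalence = 0.01, alpha = 1e-7, sided = "two",
                 e_case = 0.05, e_control = 0.05)
```

At these settings power is 77%; with 5,000 per group it is 95% at 10%
error and 77% even at 15% error — larger, noisier self-reported cohorts
can out-power smaller, cleanly phenotyped ones. The worked scenarios
above state no prevalence; the package uses 1% as a generic disease
prevalence (power varies by well under one percentage point below ~2%,
so the choice is not load-bearing). Phenotyping error is applied
symmetrically there, and the genome-wide threshold treated as
two-sided; both are arguments, not constants.

Power for quantitative traits is out of scope (replication expectations
are computed for binary traits only).

## Expected replications and prediction intervals

Each attempted replication is an independent Bernoulli trial with
success probability equal to its power. `poisson_binomial_dp()`
computes the exact distribution of the total by dynamic programming
(the recurrence $f_i(k) = f_{i-1}(k)(1-p_i) + f_{i-1}(k-1)p_i$), with
no normal approximation. The 95% prediction interval takes the largest
L with P(X < L) ≤ 2.5% and the smallest U with P(X > U) ≤ 2.5% (weak
inequalities, so the interval is deterministic and covers at least
95%). Ratio intervals divide L and U by the expected count, matching
how success ratios are reported per disease class
(`aggregate_by_class()`), with support for excluding associations whose
power is knowingly overestimated (e.g. known conflicting evidence).
`expected_directionality()` re-runs the machinery at α = 0.5 among
non-replicated associations to ask how often the direction of effect
alone should agree.

```{r expectation}
powers <- c(0.9, 0.8, 0.3)
success_ratio_summary(powers, observed = 2)
```

## The synthetic-data generator

No deposited data exist for the kind of consumer cohort this pipeline
targets, so `gen_catalog()`, `gen_cohort()` and `gen_surveys()` emulate
the generative assumptions directly: HWE genotypes at stated
risk-allele frequencies; binary disease through the logit-additive
penetrance model at stated prevalence; reported status flipping true
cases with probability `e_case` and true controls with `e_control`;
quantitative traits with unit-normal noise; proxy genotypes from
two-locus haplotype frequencies solved exactly for the target r²
(infeasible targets error with the feasible range); and survey answers
with configurable uncertain and inconsistent fractions. Catalog
fixtures are self-labelled with the curation outcome they must trigger,
so the curation tests are self-verifying. All output is deterministic
given the seed (sub-streams per generator are derived from it).

Two deliberate simplifications: the cohort generator flips *true*
labels at the stated rates, while the power model parameterizes the
composition of *reported* groups; the two parametrizations agree only
approximately away from rare-disease settings. Calibration checks
therefore simulate at the genotype-count level
(`simulate_trend_replicates()`, `calibrate_prediction_interval()`),
drawing reported-group genotype counts from exactly the mixture
distributions the power model assumes. And the generator makes no
attempt at realistic genome-wide LD, ascertainment, or population
structure beyond synthetic PC covariates — passing tests show the
pipeline's internal consistency, not robustness to real-cohort
artifacts.

## Numerical choices and problem sizes

* The baseline-odds root is found with `uniroot` on a bracket of
  ±700 log-odds at tolerance 1e-12.
* The trend statistic uses the N-denominator (score-test) variance;
  z² equals the textbook trend chi-square.
* Degenerate designs (empty group, monomorphic SNP, zero-variance
  trait) return flagged untestable results rather than errors.
* Quasi-complete separation in the OR fit is flagged with a (0, ∞)
  interval; no Firth-type correction is applied.
* Test-suite simulations use 10,000 replicates for null-calibration
  and Monte-Carlo power checks (cohorts of 200–2,000 per group), 1,000
  whole-study replicates of 200 associations for interval calibration,
  and smaller replicate counts for regression-level checks; these sizes
  give Monte-Carlo standard errors well below the tolerances asserted.
  Null-uniformity (Kolmogorov-Smirnov) checks run at 1,000 per group
  because the discrete p-value distribution at very small n has a
  visible point mass at 0.5.
* Monte-Carlo comparisons across a grid of conditions use a
  family-wise (Bonferroni-adjusted) bound plus an aggregate mean-bias
  check, so a correct implementation is not flagged by multiplicity.

## Limitations

The power model is asymptotic; at very small samples (tens per group)
its bias, though small (measured ≈ 0.002 at 200 per group), is real.
Per-disease prevalence is a required input — published tables rarely
state the values used, so per-association power for a real catalog
depends on the analyst's prevalence choices. The curation stage trusts
its inputs for LD (r² is consumed, never computed) and leaves
strand-ambiguous SNPs to manual review rather than attempting
frequency-based auto-resolution.
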