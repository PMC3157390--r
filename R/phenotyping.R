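# Case/control assignment from self-reported survey answers, with
# exclusion of uncertain or inconsistent responders and onset, sex,
# smoking and incidence-based age restrictions.

#' Define a phenotype from survey questions
#'
#' @param phenotype Phenotype label.
#' @param question_ids Nonempty character vector of question ids probing
#'   this diagnosis.
#' @param min_onset_age,max_onset_age Optional onset-age window (years)
#'   for cases, e.g. \code{max_onset_age = 17} for a juvenile-onset
#'   condition.
#' @param sex_restriction Optional \code{"male"} or \code{"female"}.
#' @param smoking_restriction Optional logical: restrict both groups to
#'   smokers (TRUE) or never-smokers (FALSE).
#' @param control_age_rule Optional [incidence_curve()] activating the
#'   residual-risk control age restriction.
#' @return A \code{phenotype_definition} list.
#' @export
phenotype_definition <- function(phenotype, question_ids,
                                 min_onset_age = NULL, max_onset_age = NULL,
                                 sex_restriction = NULL,
                                 smoking_restriction = NULL,
                                 control_age_rule = NULL) {
  stopifnot(length(question_ids) >= 1)
  if (!is.null(sex_restriction))
    stopifnot(sex_restriction %in% c("male", "female"))
  structure(list(phenotype = phenotype, question_ids = question_ids,
                 min_onset_age = min_onset_age,
                 max_onset_age = max_onset_age,
                 sex_restriction = sex_restriction,
                 smoking_restriction = smoking_restriction,
                 control_age_rule = control_age_rule),
            class = "phenotype_definition")
}

#' Cumulative incidence curve
#'
#' Tabulated cumulative incidence by age, interpolated piecewise-linearly
#' between the tabulated ages; the last value is the lifetime cumulative
#' incidence. Below the first age the curve is linear from (0, 0); above
#' the last age it is flat.
#'
#' @param ages Increasing ages in years.
#' @param cum_incidence Nondecreasing cumulative incidence in \[0, 1\].
#' @return An \code{incidence_curve} object.
#' @export
incidence_curve <- function(ages, cum_incidence) {
  stopifnot(length(ages) == length(cum_incidence),
            !is.unsorted(ages, strictly = TRUE),
            !is.unsorted(cum_incidence),
            all(cum_incidence >= 0 & cum_incidence <= 1))
  structure(list(ages = ages, cum_incidence = cum_incidence),
            class = "incidence_curve")
}

#' Evaluate a cumulative incidence curve
#'
#' @param curve An [incidence_curve()].
#' @param age Ages (years) at which to evaluate.
#' @return Cumulative incidence F(age).
#' @export
cum_incidence_at <- function(curve, age) {
  stopifnot(inherits(curve, "incidence_curve"))
  stats::approx(x = c(0, curve$ages), y = c(0, curve$cum_incidence),
                xout = pmax(age, 0), rule = 2, ties = "ordered")$y
}

#' Residual lifetime disease risk at a given age
#'
#' The probability that a currently unaffected person of the given age
#' will ever develop the disease:
#' \eqn{(F_\infty - F(a)) / (1 - F(a))}.
#'
#' @inheritParams cum_incidence_at
#' @return Residual risk in \[0, 1\].
#' @export
residual_risk <- function(curve, age) {
  f_a <- cum_incidence_at(curve, age)
  f_inf <- curve$cum_incidence[length(curve$cum_incidence)]
  (f_inf - f_a) / (1 - f_a)
}

#' Assign case/control status from survey responses
#'
#' A subject answering affirmatively to at least one of the phenotype's
#' questions (and negatively to none) is a case; a subject answering
#' negatively to at least one (and affirmatively to none) is a control;
#' a subject mixing affirmative and negative answers within the
#' phenotype's question set is excluded as inconsistent; a subject with
#' only uncertain/declined answers, or no answer at all, is excluded.
#'
#' @param responses Data frame with columns \code{subject_id},
#'   \code{question_id}, \code{answer} (one of \code{affirmative},
#'   \code{negative}, \code{uncertain}, \code{declined}) and optionally
#'   \code{onset_age}.
#' @param defn A [phenotype_definition()].
#' @param subjects Optional character vector of all subject ids;
#'   defaults to those appearing in \code{responses}.
#' @return Data frame with \code{subject_id}, \code{phenotype},
#'   \code{status} (\code{case}/\code{control}/\code{excluded}) and
#'   \code{reason} (the rule that fired).
#' @export
assign_case_control <- function(responses, defn, subjects = NULL) {
  stopifnot(inherits(defn, "phenotype_definition"),
            all(c("subject_id", "question_id", "answer")
                %in% names(responses)))
  stopifnot(all(responses$answer %in%
                  c("affirmative", "negative", "uncertain", "declined")))
  rel <- responses[responses$question_id %in% defn$question_ids, ,
                   drop = FALSE]
  if (is.null(subjects)) subjects <- unique(rel$subject_id)
  n_aff <- tapply(rel$answer == "affirmative", rel$subject_id, sum)
  n_neg <- tapply(rel$answer == "negative", rel$subject_id, sum)
  aff <- n_aff[subjects]; aff[is.na(aff)] <- 0
  neg <- n_neg[subjects]; neg[is.na(neg)] <- 0
  answered <- subjects %in% rel$subject_id

  status <- rep("excluded", length(subjects))
  reason <- rep("no_response", length(subjects))
  reason[answered & aff == 0 & neg == 0] <- "uncertain_only"
  inc <- aff > 0 & neg > 0
  status[inc] <- "excluded"; reason[inc] <- "inconsistent"
  is_case <- aff > 0 & neg == 0
  status[is_case] <- "case"; reason[is_case] <- "affirmative_answer"
  is_ctrl <- aff == 0 & neg > 0
  status[is_ctrl] <- "control"; reason[is_ctrl] <- "negative_answers"
  data.frame(subject_id = subjects, phenotype = defn$phenotype,
             status = status, reason = reason)
}

#' Apply onset-age, sex and smoking restrictions
#'
#' Cases whose reported onset age falls outside the definition's onset
#' window are excluded (e.g. adult-onset reports for a juvenile-onset
#' condition); subjects violating a sex or smoking restriction are
#' excluded from both groups.
#'
#' @param assignments Output of [assign_case_control()].
#' @param responses Survey responses (for \code{onset_age}, taken as the
#'   minimum reported over the phenotype's questions).
#' @param defn A [phenotype_definition()].
#' @param covariates Data frame with \code{subject_id} and, as needed,
#'   \code{sex} (\code{"male"}/\code{"female"}) and \code{smoker}
#'   (logical).
#' @return Updated assignments.
#' @export
apply_onset_and_matching <- function(assignments, responses, defn,
                                     covariates = NULL) {
  stopifnot(inherits(defn, "phenotype_definition"))
  out <- assignments
  if (!is.null(defn$min_onset_age) || !is.null(defn$max_onset_age)) {
    rel <- responses[responses$question_id %in% defn$question_ids &
                       !is.na(responses$onset_age), , drop = FALSE]
    onset <- tapply(rel$onset_age, rel$subject_id, min)
    o <- onset[out$subject_id]
    lo <- if (is.null(defn$min_onset_age)) -Inf else defn$min_onset_age
    hi <- if (is.null(defn$max_onset_age)) Inf else defn$max_onset_age
    bad <- out$status == "case" & (is.na(o) | o < lo | o > hi)
    out$status[bad] <- "excluded"
    out$reason[bad] <- "onset_outside_window"
  }
  if (!is.null(defn$sex_restriction)) {
    sex <- covariates$sex[match(out$subject_id, covariates$subject_id)]
    bad <- out$status != "excluded" &
      (is.na(sex) | sex != defn$sex_restriction)
    out$status[bad] <- "excluded"
    out$reason[bad] <- "sex_restriction"
  }
  if (!is.null(defn$smoking_restriction)) {
    smoker <- covariates$smoker[match(out$subject_id,
                                      covariates$subject_id)]
    bad <- out$status != "excluded" &
      (is.na(smoker) | smoker != defn$smoking_restriction)
    out$status[bad] <- "excluded"
    out$reason[bad] <- "smoking_restriction"
  }
  out
}

#' Restrict controls to ages of low residual disease risk
#'
#' For diseases with late onset, a young unaffected subject may still
#' develop the disease; such subjects dilute the control group. Controls
#' are required to be old enough that their residual lifetime risk
#' (computed from the incidence curve) is at most \code{residual_max},
#' i.e. at least \eqn{1 - residual\_max} of retained controls are
#' expected never to develop the disease. Cases are never touched; if
#' the lifetime risk is already at or below \code{residual_max}, no
#' control is excluded.
#'
#' @param assignments Output of [assign_case_control()].
#' @param ages Named numeric vector (or data frame with
#'   \code{subject_id}, \code{age}): attained age per subject.
#' @param curve An [incidence_curve()] for the disease.
#' @param residual_max Largest acceptable residual risk, default 0.10.
#' @return Updated assignments.
#' @export
restrict_controls_by_age <- function(assignments, ages, curve,
                                     residual_max = 0.10) {
  stopifnot(inherits(curve, "incidence_curve"))
  if (is.data.frame(ages))
    ages <- stats::setNames(ages$age, ages$subject_id)
  f_inf <- curve$cum_incidence[length(curve$cum_incidence)]
  if (f_inf <= residual_max) return(assignments)
  out <- assignments
  ctrl <- which(out$status == "control")
  a <- ages[out$subject_id[ctrl]]
  missing_age <- is.na(a)
  risk <- rep(NA_real_, length(ctrl))
  risk[!missing_age] <- residual_risk(curve, a[!missing_age])
  drop <- missing_age | risk > residual_max
  out$status[ctrl[drop]] <- "excluded"
  out$reason[ctrl[drop]] <- ifelse(missing_age[drop], "missing_age",
                                   "residual_risk_too_high")
  out
}
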