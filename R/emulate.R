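# Trial emulation: eligibility screening and clone-censor over the grace
# period. Each eligible patient contributes one clone per protocol arm;
# clones are artificially censored when the patient's observed treatment
# timing deviates from the arm's strategy.

eligibility_rules <- c("hospital_acquired", "readmission",
                       "pre_admission_treatment", "outcome_day0")

#' Apply eligibility and exclusion rules
#'
#' Excludes patients with hospital-acquired infection, readmissions, patients
#' treated before admission, and patients with an absorbing outcome on the
#' admission day. Rules are applied in that order and each excluded patient
#' is logged once, under the first rule it violates.
#'
#' @param patients a cohort data.frame carrying the four `flag_*` columns and
#'   the trajectory columns.
#' @param rules character vector of rule names, in application order.
#' @return list with `eligible` (the retained cohort rows) and `exclusions`
#'   (data.frame of per-rule removal counts).
#' @examples
#' coh <- generate_cohort(sim_config(n_patients = 200, seed = 3))
#' el <- apply_eligibility(coh)
#' el$exclusions
#' @export
apply_eligibility <- function(patients, rules = eligibility_rules) {
  check_cols(patients, paste0("flag_", rules), "cohort")
  nr <- length(rules)
  violates <- matrix(FALSE, nrow(patients), nr, dimnames = list(NULL, rules))
  for (k in seq_len(nr)) {
    v <- patients[[paste0("flag_", rules[k])]]
    if (rules[k] == "outcome_day0")
      v <- v | (!is.na(patients$event_day) & patients$event_day == 0L)
    violates[, k] <- v
  }
  # first violated rule per patient (0 = none), counted once per patient
  first_rule <- max.col(cbind(violates, TRUE) *
                          matrix(rep((nr + 1):1, each = nrow(violates)),
                                 nrow(violates)), ties.method = "first")
  first_rule[first_rule == nr + 1L] <- 0L
  counts <- vapply(seq_len(nr), function(k) sum(first_rule == k), integer(1))
  eligible <- patients[first_rule == 0L, , drop = FALSE]
  rownames(eligible) <- NULL
  list(eligible = eligible,
       exclusions = data.frame(rule = rules, n_excluded = counts))
}

#' Emulation settings
#'
#' @param grace_days length of the treatment-initiation grace period (days).
#' @param admin_censor_day administrative censoring horizon (days).
#' @return list of class `emulation_config`.
#' @export
emulation_config <- function(grace_days = 5L, admin_censor_day = 45L) {
  grace_days <- as.integer(grace_days)
  admin_censor_day <- as.integer(admin_censor_day)
  if (grace_days < 1L || grace_days >= admin_censor_day)
    stopf("configuration error: need 1 <= grace_days < admin_censor_day")
  structure(list(grace_days = grace_days, admin_censor_day = admin_censor_day),
            class = "emulation_config")
}

#' Clone each eligible patient into both arms and apply artificial censoring
#'
#' Every patient contributes one clone to the treated arm and one to the
#' control arm at admission (day 0). During the grace period clones are
#' censored when they deviate from their arm's strategy:
#' \itemize{
#'   \item control clone: censored at the treatment day if treatment starts
#'     within the grace period (day-0 initiation censors at day 1, the entry
#'     to the first risk interval); treatment after the grace period means
#'     the patient belongs to the control arm and causes no censoring;
#'   \item treated clone: censored at the end of the grace period if the
#'     patient is still in a transient state there without having started
#'     treatment; uncensored if treatment started within the grace period;
#'   \item a patient reaching an absorbing state within the grace period
#'     before treatment ends both clones at the event, with no artificial
#'     censoring (protocol adherence is vacuously complete). A treatment dose
#'     recorded on the event day is taken to precede the event, so such ties
#'     censor the control clone and leave the treated clone with the event.
#' }
#'
#' @param patients eligible cohort rows (see [apply_eligibility()]).
#' @param config an [emulation_config()].
#' @return A data.frame of class `ccw_clones`, two rows per patient, with
#'   columns `patient_id`, `arm`, `censor_day`, `censor_indicator`,
#'   `followup_end`, `end_reason` (`event`, `artificial_censor` or
#'   `administrative`), `terminal_state`, the clone-truncated trajectory
#'   columns and the copied baseline covariates.
#' @export
clone_and_censor <- function(patients, config = emulation_config()) {
  check_cols(patients,
             c("patient_id", "treatment_day", "icu_day", "event_day",
               "event_state"), "cohort")
  if (any(!is.na(patients$treatment_day) & patients$treatment_day < 0) ||
      any(!is.na(patients$event_day) & patients$event_day < 0))
    stopf("schema error: negative day values in cohort")
  grace <- config$grace_days
  admin <- config$admin_censor_day
  n <- nrow(patients)
  td <- patients$treatment_day
  ev <- patients$event_day

  one_arm <- function(arm) {
    cens <- rep(FALSE, n)
    cday <- rep(NA_integer_, n)
    if (arm == "control") {
      # censored at the treatment day when treatment starts in the grace
      # period and no event precedes it (tie: treatment acts first)
      cens <- !is.na(td) & td <= grace & (is.na(ev) | td <= ev)
      cday[cens] <- pmax(td[cens], 1L)
    } else {
      treated_in_grace <- !is.na(td) & td <= grace
      event_in_grace <- !is.na(ev) & ev <= grace & !treated_in_grace
      cens <- !treated_in_grace & !event_in_grace
      cday[cens] <- grace
    }
    fup <- ifelse(cens, cday, pmin(ifelse(is.na(ev), admin, ev), admin))
    reason <- ifelse(cens, "artificial_censor",
                     ifelse(!is.na(ev) & ev <= admin, "event",
                            "administrative"))
    # trajectory truncated at the clone's follow-up end; censoring (artificial
    # or administrative) never yields a same-day observed transition
    icu_day <- ifelse(!is.na(patients$icu_day) & patients$icu_day < fup,
                      patients$icu_day, NA_integer_)
    event_day <- ifelse(reason == "event", ev, NA_integer_)
    event_state <- ifelse(reason == "event", patients$event_state, NA_integer_)
    terminal <- state_at_day(fup, icu_day, event_day, event_state)
    data.frame(patient_id = patients$patient_id, arm = arm,
               censor_day = cday, censor_indicator = as.integer(cens),
               followup_end = as.integer(fup), end_reason = reason,
               terminal_state = terminal,
               icu_day = as.integer(icu_day),
               event_day = as.integer(event_day),
               event_state = as.integer(event_state))
  }

  covars <- patients[, covariate_columns(patients), drop = FALSE]
  out <- rbind(cbind(one_arm("treated"), covars),
               cbind(one_arm("control"), covars))
  rownames(out) <- NULL
  out$clone_id <- seq_len(nrow(out))
  attr(out, "grace_days") <- grace
  attr(out, "admin_censor_day") <- admin
  class(out) <- c("ccw_clones", "data.frame")
  out
}

covariate_columns <- function(df) {
  intersect(c("age", "sex", "charlson_ge2", "crp", "ldh", "log_ddimer",
              "lymphocytes", "wave"), names(df))
}
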