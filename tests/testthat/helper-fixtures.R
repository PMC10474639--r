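# Build small cohorts by hand: fills in neutral covariates and flags so a
# test only states what it cares about (treatment/event timing).
toy_patients <- function(n = 1, treatment_day = NA_integer_,
                         icu_day = NA_integer_, event_day = NA_integer_,
                         event_state = NA_integer_,
                         flags = NULL) {
  df <- data.frame(
    patient_id = seq_len(n),
    age = 65, sex = rep_len(c(0, 1), n), charlson_ge2 = 0,
    crp = 80, ldh = 300, log_ddimer = log(600), lymphocytes = 1000,
    wave = 1L,
    treatment_day = as.integer(rep_len(treatment_day, n)),
    icu_day = as.integer(rep_len(icu_day, n)),
    event_day = as.integer(rep_len(event_day, n)),
    event_state = as.integer(rep_len(event_state, n)),
    flag_hospital_acquired = FALSE, flag_readmission = FALSE,
    flag_pre_admission_treatment = FALSE, flag_outcome_day0 = FALSE)
  df$history <- format_history(df$icu_day, df$event_day, df$event_state)
  if (!is.null(flags)) for (nm in names(flags)) df[[nm]] <- flags[[nm]]
  attr(df, "admin_censor_day") <- 45L
  attr(df, "grace_days") <- 5L
  class(df) <- c("ccw_cohort", "data.frame")
  df
}

# Assemble an ordinal-outcome table directly from category codes per arm.
make_outcomes <- function(categories_treated, categories_control,
                          weights = 1) {
  n <- length(categories_treated) + length(categories_control)
  data.frame(clone_id = seq_len(n),
             arm = rep(c("treated", "control"),
                       c(length(categories_treated),
                         length(categories_control))),
             evaluation_day = 30,
             category = factor(c(categories_treated, categories_control),
                               levels = 1:5,
                               labels = c("home", "ward", "hcf", "icu",
                                          "death"), ordered = TRUE),
             weight = rep_len(weights, n))
}

fit_both_arms <- function(clones, ...) {
  list(treated = fit_censoring_model(clones[clones$arm == "treated", ,
                                            drop = FALSE], ...),
       control = fit_censoring_model(clones[clones$arm == "control", ,
                                            drop = FALSE], ...))
}
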