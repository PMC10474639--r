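# Synthetic hospitalized-cohort simulator.
#
# Discrete integer-day simulation of a five-state forward-only hospital
# course with covariate-dependent (confounded) treatment initiation during a
# grace period. All hazards are daily transition probabilities; competing
# destinations within a day are drawn from one categorical distribution per
# patient-day, so they are mutually exclusive by construction.

std_covariate_names <- c("z_age", "sex", "charlson_ge2", "z_crp", "z_ldh",
                         "z_log_ddimer", "z_lymphocytes", "wave2", "wave3")

default_covariate_params <- function() {
  list(age = c(mean = 65, sd = 12),
       sex_prob = 0.60,
       charlson_ge2_prob = 0.45,
       crp = c(meanlog = log(80), sdlog = 0.8),          # mg/L
       ldh = c(meanlog = log(300), sdlog = 0.4),         # U/L
       ddimer = c(meanlog = log(600), sdlog = 0.9),      # ng/mL (stored logged)
       lymphocytes = c(meanlog = log(1000), sdlog = 0.5),# x10^6/L
       wave_probs = c(0.45, 0.35, 0.20))
}

# Treatment initiation is confounded: older patients and patients with higher
# inflammation markers are more likely to receive the dose, and initiation
# becomes less likely as days pass. Log odds per standard deviation are in
# the 0.2-0.35 range typical of treatment-choice models in hospital cohorts.
default_initiation_coefs <- function() {
  c(intercept = -2.9, day = -0.15,
    z_age = 0.3, sex = 0.1, charlson_ge2 = 0.3, z_crp = 0.35, z_ldh = 0.2,
    z_log_ddimer = 0.2, z_lymphocytes = -0.2, wave2 = -0.2, wave3 = -0.3)
}

default_hazard_spec <- function() {
  transitions <- data.frame(
    from = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    to   = c(2L, 3L, 4L, 5L, 3L, 4L, 5L),
    base_prob = c(0.024, 0.016, 0.026, 0.015, 0.045, 0.012, 0.020),
    trt_loghr = 0)
  loghr <- matrix(0, nrow = 7, ncol = length(std_covariate_names),
                  dimnames = list(paste0(transitions$from, "->", transitions$to),
                                  std_covariate_names))
  # Severity markers push towards ICU/death and away from discharge home;
  # effects are per standard deviation of the marker.
  loghr["1->2", ] <- c( 0.25, 0.10, 0.20,  0.30, 0.15,  0.20, -0.20, 0, 0)
  loghr["1->3", ] <- c( 0.35, 0.10, 0.30,  0.30, 0.20,  0.25, -0.25, -0.05, -0.10)
  loghr["1->4", ] <- c(-0.20, 0.00, -0.15, -0.15, -0.10, -0.10, 0.15, 0.05, 0.05)
  loghr["1->5", ] <- c( 0.25, 0.00, 0.20, 0.05, 0.05, 0.05, -0.05, 0, 0)
  loghr["2->3", ] <- c( 0.30, 0.10, 0.25,  0.20, 0.15,  0.20, -0.20, -0.05, -0.10)
  loghr["2->4", ] <- c(-0.15, 0.00, -0.10, -0.10, -0.05, -0.10, 0.10, 0, 0)
  loghr["2->5", ] <- c( 0.20, 0.00, 0.15, 0.05, 0.05, 0.05, -0.05, 0, 0)
  list(transitions = transitions, covariate_loghr = loghr)
}

#' Simulation configuration for the synthetic hospitalized cohort
#'
#' Assembles and validates the parameters of the discrete-day cohort
#' simulator: baseline covariate distributions (age in years; sex and
#' dichotomized Charlson comorbidity index as Bernoulli; log-normal
#' C-reactive protein, lactate dehydrogenase, D-dimer and lymphocyte count;
#' pandemic-wave category), log-odds coefficients linking covariates to the
#' daily treatment-initiation probability, per-transition daily baseline
#' probabilities with covariate and treatment log hazard ratios, the
#' administrative censoring day, and the fractions of deliberately ineligible
#' records injected for exercising the exclusion rules.
#'
#' @param n_patients number of records to generate.
#' @param seed integer seed driving all randomness of [generate_cohort()].
#' @param covariate_params,initiation_coefs,hazard_spec,ineligible_fractions
#'   overrides of the defaults; partial lists are merged over the defaults.
#' @param admin_censor_day administrative censoring horizon in days.
#' @param grace_days treatment-initiation grace period in days.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 1)
#' cfg$hazard_spec$transitions
#' @export
sim_config <- function(n_patients, seed,
                       covariate_params = list(),
                       initiation_coefs = NULL,
                       hazard_spec = NULL,
                       admin_censor_day = 45L,
                       grace_days = 5L,
                       ineligible_fractions = NULL) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0)
    stopf("configuration error: 'n_patients' must be a nonnegative integer")
  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  ic <- default_initiation_coefs()
  if (!is.null(initiation_coefs)) ic[names(initiation_coefs)] <- initiation_coefs
  hs <- if (is.null(hazard_spec)) default_hazard_spec() else hazard_spec
  fr <- c(hospital_acquired = 0.03, readmission = 0.02,
          pre_admission_treatment = 0.01, outcome_day0 = 0.008)
  if (!is.null(ineligible_fractions)) fr[names(ineligible_fractions)] <- ineligible_fractions

  check_prob(cp$sex_prob, "covariate_params$sex_prob")
  check_prob(cp$charlson_ge2_prob, "covariate_params$charlson_ge2_prob")
  check_prob(cp$wave_probs, "covariate_params$wave_probs")
  if (abs(sum(cp$wave_probs) - 1) > 1e-8)
    stopf("configuration error: 'covariate_params$wave_probs' must sum to 1")
  check_prob(fr, "ineligible_fractions")
  check_prob(hs$transitions$base_prob, "hazard_spec$transitions$base_prob")

  structure_default <- transition_structure()
  key <- function(df) paste(df$from, df$to, sep = "->")
  if (!setequal(key(hs$transitions),
                paste(structure_default$allowed[, 1],
                      structure_default$allowed[, 2], sep = "->")))
    stopf("configuration error: 'hazard_spec' must cover exactly the allowed transition set")
  for (s in structure_default$transient) {
    if (sum(hs$transitions$base_prob[hs$transitions$from == s]) >= 1)
      stopf("configuration error: total daily exit probability from state %d is >= 1", s)
  }
  if (grace_days >= admin_censor_day)
    stopf("configuration error: 'grace_days' must be below 'admin_censor_day'")

  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 covariate_params = cp, initiation_coefs = ic, hazard_spec = hs,
                 admin_censor_day = as.integer(admin_censor_day),
                 grace_days = as.integer(grace_days),
                 ineligible_fractions = fr),
            class = "sim_config")
}

# Standardized covariate scores used in the simulator's linear predictors,
# built from the theoretical moments of the generating distributions.
# The initiation model is linear on the raw marker scale ("raw"), matching
# the functional form of the censoring models fitted by the analysis (CRP,
# LDH and lymphocytes enter linearly, D-dimer logged); transition hazards
# use log-scale scores ("log"), which keeps exp(loghr . z) bounded under the
# markers' heavy right tails.
covariate_scores <- function(df, config, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  cp <- config$covariate_params
  zmark <- function(x, p) {
    if (scale == "log") {
      (log(x) - p[["meanlog"]]) / p[["sdlog"]]
    } else {
      m <- exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
      (x - m) / (m * sqrt(exp(p[["sdlog"]]^2) - 1))
    }
  }
  cbind(z_age = (df$age - cp$age[["mean"]]) / cp$age[["sd"]],
        sex = df$sex,
        charlson_ge2 = df$charlson_ge2,
        z_crp = zmark(df$crp, cp$crp),
        z_ldh = zmark(df$ldh, cp$ldh),
        z_log_ddimer = (df$log_ddimer - cp$ddimer[["meanlog"]]) / cp$ddimer[["sdlog"]],
        z_lymphocytes = zmark(df$lymphocytes, cp$lymphocytes),
        wave2 = as.numeric(df$wave == 2L),
        wave3 = as.numeric(df$wave == 3L))
}

draw_covariates <- function(n, config) {
  cp <- config$covariate_params
  data.frame(
    age = pmax(18, rnorm(n, cp$age[["mean"]], cp$age[["sd"]])),
    sex = rbinom(n, 1L, cp$sex_prob),
    charlson_ge2 = rbinom(n, 1L, cp$charlson_ge2_prob),
    crp = rlnorm(n, cp$crp[["meanlog"]], cp$crp[["sdlog"]]),
    ldh = rlnorm(n, cp$ldh[["meanlog"]], cp$ldh[["sdlog"]]),
    log_ddimer = rnorm(n, cp$ddimer[["meanlog"]], cp$ddimer[["sdlog"]]),
    lymphocytes = rlnorm(n, cp$lymphocytes[["meanlog"]], cp$lymphocytes[["sdlog"]]),
    wave = sample.int(3L, n, replace = TRUE, prob = cp$wave_probs))
}

#' Simulate covariate-dependent treatment-initiation days
#'
#' Each day `d = 0, 1, ...` up to the administrative horizon, a not yet
#' treated patient initiates treatment with probability
#' `plogis(intercept + coefs . z + day_coef * d)`; the first success is the
#' (potential) initiation day. Initiation is allowed after the grace period
#' (such patients are later classified in the control arm), and
#' [generate_cohort()] discards initiation days falling after the patient's
#' absorbing event.
#'
#' @param covariates data.frame of baseline covariates (as produced by
#'   [generate_cohort()]).
#' @param config a [sim_config()].
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return integer vector of initiation days (NA if never initiated).
#' @export
simulate_treatment_initiation <- function(covariates, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(covariates)
    if (n == 0L) return(integer(0))
    ic <- config$initiation_coefs
    z <- covariate_scores(covariates, config, scale = "raw")
    lp0 <- ic[["intercept"]] + drop(z %*% ic[std_covariate_names])
    days <- 0:config$admin_censor_day
    # n x days matrix of daily initiation probabilities and uniforms
    p <- plogis(outer(lp0, ic[["day"]] * days, `+`))
    u <- matrix(runif(n * length(days)), nrow = n)
    hit <- u < p
    first <- apply(hit, 1L, function(r) which(r)[1L])
    as.integer(days[first])
  })
}

#' Simulate multi-state hospital trajectories
#'
#' Discrete-day competing-risks simulation over the five-state forward-only
#' structure: each day, a patient in transient state `l` moves to destination
#' `m` with daily cause-specific probability
#' `base_prob_lm * exp(loghr_lm . z + trt_loghr_lm * treated(t))`, where
#' `treated(t)` is 1 from the initiation day onward (inclusive: a dose
#' recorded on an event day is taken to act before the event). Draws among
#' competing destinations come from a single categorical draw per day, and
#' trajectories still in a transient state at the administrative horizon are
#' truncated there.
#'
#' @param covariates data.frame of baseline covariates.
#' @param treatment_day integer vector of initiation days (NA for never);
#'   recycled if length 1.
#' @param config a [sim_config()] carrying the hazard specification.
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return data.frame with columns `icu_day`, `event_day`, `event_state`
#'   (NA where absent) and the serialized `history` string.
#' @export
simulate_trajectory <- function(covariates, treatment_day, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(covariates)
    out <- data.frame(icu_day = rep(NA_integer_, n),
                      event_day = rep(NA_integer_, n),
                      event_state = rep(NA_integer_, n))
    if (n == 0L) {
      out$history <- character(0)
      return(out)
    }
    treatment_day <- rep_len(as.integer(treatment_day), n)
    hs <- config$hazard_spec
    tr <- hs$transitions
    z <- covariate_scores(covariates, config, scale = "log")
    # per-patient multiplicative covariate effect, one column per transition
    mult <- exp(z %*% t(hs$covariate_loghr))
    trt_mult <- exp(tr$trt_loghr)
    trans_idx <- split(seq_len(nrow(tr)), tr$from)

    state <- rep(1L, n)
    horizon <- config$admin_censor_day
    for (t in seq_len(horizon)) {
      state_start <- state  # at most one transition per patient-day
      for (from in names(trans_idx)) {
        idx <- trans_idx[[from]]
        here <- which(state_start == as.integer(from))
        if (!length(here)) next
        treated <- !is.na(treatment_day[here]) & treatment_day[here] <= t
        p <- sweep(mult[here, idx, drop = FALSE], 2L, tr$base_prob[idx], `*`)
        if (any(treated))
          p[treated, ] <- sweep(p[treated, , drop = FALSE], 2L, trt_mult[idx], `*`)
        tot <- rowSums(p)
        if (any(tot >= 1))
          stopf(paste("simulation error: total daily exit probability >= 1",
                      "for state %s at day %d; rescale 'hazard_spec' baseline",
                      "probabilities or covariate log hazard ratios"),
                from, t)
        u <- runif(length(here))
        cum <- p
        for (j in seq_len(ncol(p))[-1L]) cum[, j] <- cum[, j] + cum[, j - 1L]
        dest_j <- rowSums(u >= cbind(0, cum[, -ncol(cum), drop = FALSE])) *
          (u < cum[, ncol(cum)])
        moved <- which(dest_j > 0)
        if (length(moved)) {
          who <- here[moved]
          to <- tr$to[idx][dest_j[moved]]
          is_icu <- to == 2L
          out$icu_day[who[is_icu]] <- t
          out$event_day[who[!is_icu]] <- t
          out$event_state[who[!is_icu]] <- to[!is_icu]
          state[who] <- to
        }
      }
      if (all(state %in% c(3L, 4L, 5L))) break
    }
    out$history <- format_history(out$icu_day, out$event_day, out$event_state)
    out
  })
}

#' Generate a synthetic hospitalized cohort
#'
#' Draws baseline covariates, eligibility-violation flags, a confounded
#' treatment-initiation day and a multi-state hospital trajectory for each
#' patient. Initiation days falling after the patient's absorbing event are
#' discarded (treatment cannot be given after death or discharge); a day that
#' ties with the event is kept, matching the emulation tie rule that a dose
#' recorded on the event day was administered first.
#'
#' @param config a [sim_config()].
#' @return A data.frame of class `ccw_cohort`, one row per patient, with the
#'   baseline covariates, `treatment_day` (NA if never treated within
#'   follow-up), the trajectory columns `icu_day`/`event_day`/`event_state`,
#'   the serialized `history`, and four logical eligibility-violation flags.
#' @examples
#' coh <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' table(is.na(coh$treatment_day))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("configuration error: 'config' must be a sim_config object")
  n <- config$n_patients
  with_seed(config$seed, {
    cov <- draw_covariates(n, config)
    fr <- config$ineligible_fractions
    flags <- data.frame(
      flag_hospital_acquired = runif(n) < fr[["hospital_acquired"]],
      flag_readmission = runif(n) < fr[["readmission"]],
      flag_pre_admission_treatment = runif(n) < fr[["pre_admission_treatment"]],
      flag_outcome_day0 = runif(n) < fr[["outcome_day0"]])
    potential <- simulate_treatment_initiation(cov, config)
    traj <- simulate_trajectory(cov, potential, config)
    td <- potential
    after_event <- !is.na(td) & !is.na(traj$event_day) & td > traj$event_day
    td[after_event] <- NA_integer_
    out <- cbind(data.frame(patient_id = seq_len(n)), cov,
                 data.frame(treatment_day = td), traj, flags)
    attr(out, "admin_censor_day") <- config$admin_censor_day
    attr(out, "grace_days") <- config$grace_days
    class(out) <- c("ccw_cohort", "data.frame")
    out
  })
}

#' Monte-Carlo oracle for true state-occupation probabilities
#'
#' Simulates `n_mc` independent trajectories under a fixed treatment policy
#' (overriding the confounded initiation process) and tabulates the state
#' occupied at the end of each day. Used as ground truth when checking that
#' the clone-censor-weight analysis recovers per-arm occupation probabilities.
#'
#' @param config a [sim_config()].
#' @param policy `"never"` for never-treat, or a nonnegative integer day `d`
#'   for treat-at-day-`d`.
#' @param n_mc number of Monte-Carlo trajectories.
#' @param seed seed for the oracle draws.
#' @return numeric matrix with rows `day 0..admin_censor_day` and one column
#'   per state (1..5); each row sums to 1.
#' @export
occupation_oracle <- function(config, policy, n_mc, seed) {
  if (n_mc < 1) stopf("configuration error: 'n_mc' must be >= 1")
  treat_day <- if (identical(policy, "never")) NA_integer_ else {
    if (!is.numeric(policy) || length(policy) != 1L || policy < 0)
      stopf("configuration error: 'policy' must be \"never\" or a nonnegative day")
    as.integer(policy)
  }
  with_seed(seed, {
    cov <- draw_covariates(n_mc, config)
    traj <- simulate_trajectory(cov, treat_day, config)
    days <- 0:config$admin_censor_day
    occ <- matrix(0, nrow = length(days), ncol = 5,
                  dimnames = list(paste0("day", days),
                                  names(transition_structure()$states)))
    for (i in seq_along(days)) {
      st <- state_at_day(days[i], traj$icu_day, traj$event_day, traj$event_state)
      occ[i, ] <- tabulate(st, nbins = 5L) / n_mc
    }
    occ
  })
}
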