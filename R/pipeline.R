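# End-to-end drivers: the full clone-censor-weight emulation with weighted
# multi-state estimation, the fast odds-ratio-only path used inside the
# bootstrap, and a deliberately naive ever-treated analysis used to
# demonstrate immortal time bias.

#' Run the clone-censor-weight emulation and weighted multi-state analysis
#'
#' Applies the exclusion rules, clones every eligible patient into both arms,
#' imposes artificial censoring over the grace period, fits the arm-specific
#' censoring models, computes the weight table and covariate balance, and
#' estimates per-arm weighted cumulative transition hazards and
#' Aalen-Johansen state-occupation probabilities.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param config an [emulation_config()].
#' @param covariate_names censoring-model covariates.
#' @param structure a [transition_structure()].
#' @param truncation_quantile weight-truncation quantile (1 = none).
#' @param stabilize use stabilized weights.
#' @return list of class `ccw_emulation` with elements `eligible`,
#'   `exclusions`, `clones`, `models`, `weights`, `balance`, and per-arm
#'   `cumhaz`, `probtrans` and `occupation` (day x state matrices).
#' @examples
#' coh <- generate_cohort(sim_config(n_patients = 300, seed = 11))
#' fit <- ccw_emulate(coh)
#' round(fit$occupation$control["day30", ], 3)
#' @export
ccw_emulate <- function(cohort, config = emulation_config(),
                        covariate_names = default_censoring_covariates,
                        structure = transition_structure(),
                        truncation_quantile = 1,
                        stabilize = FALSE) {
  el <- apply_eligibility(cohort)
  clones <- clone_and_censor(el$eligible, config)
  models <- list(
    treated = fit_censoring_model(clones[clones$arm == "treated", , drop = FALSE],
                                  covariate_names),
    control = fit_censoring_model(clones[clones$arm == "control", , drop = FALSE],
                                  covariate_names))
  weights <- compute_weights(models, clones, stabilize = stabilize)
  weights <- truncate_weights(weights, truncation_quantile)
  balance <- balance_smd(clones, weights, covariate_names)
  arms <- list()
  for (arm in c("treated", "control")) {
    sub <- clones[clones$arm == arm, , drop = FALSE]
    attr(sub, "grace_days") <- config$grace_days
    attr(sub, "admin_censor_day") <- config$admin_censor_day
    long <- build_long_format(sub, weights, structure,
                              horizon = config$admin_censor_day)
    ch <- weighted_nelson_aalen(long, structure)
    pt <- aalen_johansen(ch, structure, s = 0L,
                         horizon = config$admin_censor_day)
    arms[[arm]] <- list(cumhaz = ch, probtrans = pt,
                        occupation = state_occupation(pt))
  }
  res <- list(eligible = el$eligible, exclusions = el$exclusions,
              clones = clones, models = models, weights = weights,
              balance = balance,
              cumhaz = lapply(arms, `[[`, "cumhaz"),
              probtrans = lapply(arms, `[[`, "probtrans"),
              occupation = lapply(arms, `[[`, "occupation"),
              config = config)
  class(res) <- "ccw_emulation"
  res
}

#' @export
print.ccw_emulation <- function(x, ...) {
  cat("Clone-censor-weight emulation\n")
  cat(sprintf("  eligible patients: %d (excluded: %d)\n",
              nrow(x$eligible), sum(x$exclusions$n_excluded)))
  for (arm in c("treated", "control")) {
    cl <- x$clones[x$clones$arm == arm, ]
    cat(sprintf("  %s arm: %d clones, %d artificially censored\n",
                arm, nrow(cl), sum(cl$censor_indicator)))
  }
  cat(sprintf("  max weighted SMD at grace end: %.3f\n",
              max(x$balance$smd_weighted, na.rm = TRUE)))
  occ30 <- sapply(x$occupation, function(m)
    m[min(31L, nrow(m)), "death"])
  cat(sprintf("  day-30 death probability: treated %.3f, control %.3f\n",
              occ30[["treated"]], occ30[["control"]]))
  invisible(x)
}

# Fast path for the bootstrap: eligibility -> clones -> weights -> ordinal
# proportional-odds fit, skipping the multi-state estimators.
pipeline_odds_ratio <- function(patients, config = emulation_config(),
                                covariate_names = default_censoring_covariates,
                                evaluation_day = 30L,
                                variant = "five_level",
                                truncation_quantile = 1,
                                stabilize = FALSE) {
  el <- apply_eligibility(patients)
  clones <- clone_and_censor(el$eligible, config)
  models <- list(
    treated = fit_censoring_model(clones[clones$arm == "treated", , drop = FALSE],
                                  covariate_names),
    control = fit_censoring_model(clones[clones$arm == "control", , drop = FALSE],
                                  covariate_names))
  if (truncation_quantile < 1) {
    wt <- truncate_weights(compute_weights(models, clones,
                                           stabilize = stabilize),
                           truncation_quantile)
    key_day <- pmin(evaluation_day,
                    clones$followup_end - (clones$end_reason == "event"))
    w <- wt$weight[match(day_key(clones$clone_id, key_day),
                         day_key(wt$clone_id, wt$day))]
  } else {
    w <- clone_weight_at(models, clones, evaluation_day, stabilize = stabilize)
  }
  outcomes <- ordinal_status_at(clones, evaluation_day, variant, weights = w)
  weighted_proportional_odds(outcomes)
}

#' Naive ever-treated state-occupation analysis (biased by design)
#'
#' Groups patients by whether they ever received treatment — using
#' information from after time zero, the textbook source of immortal time
#' bias — and estimates unweighted Aalen-Johansen state-occupation
#' probabilities per group, without cloning or weighting. Provided as the
#' comparator that the clone-censor-weight pipeline corrects.
#'
#' @param cohort cohort data.frame (eligibility rules are applied first).
#' @param structure a [transition_structure()].
#' @param horizon administrative horizon.
#' @return list with per-group (`treated`, `control`) occupation matrices.
#' @export
naive_occupation <- function(cohort, structure = transition_structure(),
                             horizon = NULL) {
  if (is.null(horizon)) horizon <- attr(cohort, "admin_censor_day") %||% 45L
  el <- apply_eligibility(cohort)$eligible
  ever <- !is.na(el$treatment_day)
  out <- list()
  for (grp in c("treated", "control")) {
    sub <- el[if (grp == "treated") ever else !ever, , drop = FALSE]
    pseudo <- data.frame(
      patient_id = sub$patient_id,
      arm = grp,
      censor_day = NA_integer_, censor_indicator = 0L,
      followup_end = as.integer(pmin(ifelse(is.na(sub$event_day), horizon,
                                            sub$event_day), horizon)),
      end_reason = ifelse(!is.na(sub$event_day) & sub$event_day <= horizon,
                          "event", "administrative"),
      event_day = sub$event_day,
      event_state = sub$event_state)
    pseudo$icu_day <- ifelse(!is.na(sub$icu_day) &
                               sub$icu_day < pseudo$followup_end,
                             sub$icu_day, NA_integer_)
    pseudo$terminal_state <- state_at_day(pseudo$followup_end, pseudo$icu_day,
                                          pseudo$event_day, pseudo$event_state)
    pseudo$clone_id <- seq_len(nrow(pseudo))
    attr(pseudo, "admin_censor_day") <- horizon
    unit_w <- data.frame(clone_id = rep(pseudo$clone_id,
                                        pseudo$followup_end + 1L),
                         day = sequence(pseudo$followup_end + 1L) - 1L,
                         weight = 1)
    long <- build_long_format(pseudo, unit_w, structure, horizon)
    pt <- aalen_johansen(weighted_nelson_aalen(long, structure), structure,
                         s = 0L, horizon = horizon)
    out[[grp]] <- state_occupation(pt)
  }
  out
}
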