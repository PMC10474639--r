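# Inverse probability of artificial-censoring weights.
#
# Arm-specific Cox models for the time to artificial censoring, with a
# Breslow baseline cumulative hazard, give each clone's probability of
# remaining uncensored S_C(t | Z); unstabilized weights are 1 / S_C. The
# censoring risk sets order outcome events before censoring within a day, so
# a clone whose outcome occurs on day k leaves the censoring risk set at
# k - 1/2.

default_censoring_covariates <- c("age", "sex", "charlson_ge2", "crp", "ldh",
                                  "log_ddimer", "lymphocytes", "wave")

#' Build the censoring-model design matrix
#'
#' Expands the pandemic-wave category into `wave2`/`wave3` indicators; all
#' other covariates enter linearly (D-dimer is already log-transformed in the
#' cohort schema).
#'
#' @param df data.frame with the covariate columns.
#' @param covariate_names covariates to include; `"wave"` is expanded.
#' @return numeric matrix, one column per model term.
#' @export
build_covariate_matrix <- function(df, covariate_names = default_censoring_covariates) {
  check_cols(df, covariate_names, "covariate table")
  cols <- lapply(covariate_names, function(nm) {
    if (nm == "wave") {
      m <- cbind(wave2 = as.numeric(df$wave == 2L),
                 wave3 = as.numeric(df$wave == 3L))
    } else {
      m <- matrix(as.numeric(df[[nm]]), ncol = 1,
                  dimnames = list(NULL, nm))
    }
    m
  })
  do.call(cbind, cols)
}

# (time, status) for the censoring process of one arm's clones: artificial
# censoring is the event; outcome events within the grace period exit the
# risk set just before their day; everyone else is administratively censored
# for the censoring process at the end of the grace period.
censoring_process_times <- function(clones, grace) {
  time <- pmin(clones$followup_end, grace)
  status <- clones$censor_indicator
  ev <- status == 0L & clones$end_reason == "event" & clones$event_day <= grace
  time[ev] <- clones$event_day[ev] - 0.5
  time[status == 1L] <- clones$censor_day[status == 1L]
  data.frame(time = time, status = status)
}

#' Fit an arm-specific Cox model for the artificial-censoring hazard
#'
#' The censoring indicator is the event of interest and all other follow-up
#' ends are right-censorings of the censoring process. Ties are handled with
#' Efron's method by default: in the treated arm every artificial censoring
#' is tied at the end of the grace period, a tie mass under which Breslow's
#' approximation attenuates the coefficients badly enough to defeat the
#' covariate balance the weights exist to restore; Efron's method is accurate
#' there. `ties = "breslow"` remains available.
#'
#' @param clones clone rows of a single arm (see [clone_and_censor()]).
#' @param covariate_names covariates of the censoring model.
#' @param ties tie-handling method for the partial likelihood.
#' @return Object of class `censoring_model`: coefficients, baseline
#'   cumulative hazard step function (as `time`/`cumhaz` vectors), covariate
#'   names, fit diagnostics, and a `degenerate` flag that is TRUE when the
#'   arm has no artificial censoring at all (all weights are then 1).
#' @export
fit_censoring_model <- function(clones, covariate_names = default_censoring_covariates,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  arm <- unique(clones$arm)
  if (length(arm) != 1L)
    stopf("configuration error: fit_censoring_model() expects clones of one arm")
  grace <- attr(clones, "grace_days") %||% 5L
  X <- build_covariate_matrix(clones, covariate_names)
  cp <- censoring_process_times(clones, grace)
  base <- list(arm = arm, covariate_names = colnames(X), grace_days = grace)
  if (sum(cp$status) == 0L) {
    return(structure(c(base, list(
      degenerate = TRUE, coefficients = setNames(rep(0, ncol(X)), colnames(X)),
      baseline = data.frame(time = numeric(0), cumhaz = numeric(0)),
      fit_diagnostics = list(n = nrow(clones), nevent = 0L))),
      class = "censoring_model"))
  }
  # constant columns carry no information about the censoring hazard: their
  # coefficient is fixed at 0 and the fit runs on the remaining columns
  # (with none left, the model is null and the baseline is the Nelson-Aalen
  # of the censoring times)
  keep <- apply(X, 2L, function(v) diff(range(v)) > 0)
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  if (any(keep)) {
    fit <- survival::coxph.fit(X[, keep, drop = FALSE], Surv(cp$time, cp$status),
                               strata = NULL, offset = NULL, init = NULL,
                               control = survival::coxph.control(),
                               weights = NULL, method = ties, rownames = NULL)
    beta[keep] <- fit$coefficients
  } else {
    # null model: no scores to tie-correct, baseline is the plain
    # Nelson-Aalen of the censoring times
    fit <- list(loglik = c(NA_real_, NA_real_), iter = 0L)
    ties <- "breslow"
  }
  if (anyNA(beta))
    stopf("censoring model error: coefficient(s) inestimable for covariate(s): %s",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  if (any(abs(beta) > 15))
    stopf("censoring model error: apparent separation on covariate(s): %s",
          paste(names(beta)[abs(beta) > 15], collapse = ", "))
  lp <- drop(X %*% beta)
  structure(c(base, list(
    degenerate = FALSE, coefficients = beta,
    baseline = baseline_cumulative_hazard(cp$time, cp$status, lp, ties),
    fit_diagnostics = list(n = nrow(clones), nevent = sum(cp$status),
                           loglik = fit$loglik[2L], iter = fit$iter))),
    class = "censoring_model")
}

# Baseline cumulative hazard at the fitted coefficients: Breslow increments
# d_t / sum_{risk} exp(lp), or Efron's tie-corrected version
# sum_{j=0}^{d-1} 1 / (S_t - (j/d) D_t) with D_t the tied-event score sum.
# Matches survival::basehaz(fit, centered = FALSE) on the event-time grid.
baseline_cumulative_hazard <- function(time, status, lp, method) {
  score <- exp(lp)
  etimes <- sort(unique(time[status == 1L]))
  inc <- vapply(etimes, function(t) {
    S <- sum(score[time >= t])
    tied <- status == 1L & time == t
    d <- sum(tied)
    if (method == "efron") {
      D <- sum(score[tied])
      sum(1 / (S - (seq_len(d) - 1L) / d * D))
    } else {
      d / S
    }
  }, numeric(1))
  data.frame(time = etimes, cumhaz = cumsum(inc))
}

#' @export
print.censoring_model <- function(x, ...) {
  cat("Artificial-censoring Cox model (", x$arm, " arm)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: no artificial censoring events; all weights are 1\n")
  } else {
    print(round(x$coefficients, 4))
    cat("  events:", x$fit_diagnostics$nevent, "of", x$fit_diagnostics$n,
        "clones\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild the design matrix a censoring model was fitted on (the stored
# covariate_names are post-expansion, e.g. wave2/wave3 for the wave factor).
model_covariate_matrix <- function(model, df) {
  raw <- unique(ifelse(model$covariate_names %in% c("wave2", "wave3"),
                       "wave", model$covariate_names))
  X <- build_covariate_matrix(df, raw)
  X[, model$covariate_names, drop = FALSE]
}

# Breslow baseline cumulative hazard evaluated at (possibly fractional) t.
baseline_cumhaz_at <- function(model, t) {
  if (model$degenerate || nrow(model$baseline) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, model$baseline$time)
  c(0, model$baseline$cumhaz)[idx + 1L]
}

#' Probability of remaining uncensored
#'
#' Evaluates `S_C(t | Z) = exp(-Lambda_0C(min(t, grace)) * exp(beta_C . Z))`
#' from a fitted [fit_censoring_model()]. Equals 1 at `t = 0` and is constant
#' after the grace period.
#'
#' @param model a `censoring_model`.
#' @param Z covariate matrix (rows = clones, columns matching the model) or a
#'   single covariate vector.
#' @param t evaluation day (scalar, or vector matching `nrow(Z)`).
#' @return numeric vector of probabilities in (0, 1].
#' @export
uncensored_probability <- function(model, Z, t) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != length(model$coefficients))
    stopf("covariate vector length %d does not match model (%d)",
          ncol(Z), length(model$coefficients))
  if (any(t < 0)) stopf("'t' must be >= 0")
  lp <- drop(Z %*% model$coefficients)
  exp(-baseline_cumhaz_at(model, pmin(t, model$grace_days)) * exp(lp))
}

#' Compute the inverse-probability-of-censoring weight table
#'
#' For every clone and every day it is at risk (day 0 up to its follow-up
#' end), the unstabilized weight `W_i(t) = 1 / S_C(min(t, grace) | Z_i)` from
#' the clone's own arm's censoring model. Weights are 1 at day 0,
#' nondecreasing in `t` and constant after the grace period. With
#' `stabilize = TRUE` the numerator is the arm-specific marginal uncensored
#' probability (a null censoring model), giving mean-one style weights.
#'
#' @param models named list with elements `treated` and `control`
#'   ([fit_censoring_model()] objects; degenerate models give weight 1).
#' @param clones the full clone table.
#' @param stabilize logical; default FALSE (unstabilized, as in the primary
#'   analysis).
#' @param prob_floor lowest admissible uncensored probability; smaller values
#'   raise an error naming the extreme clones and suggesting truncation.
#' @return data.frame of class `ccw_weights` with columns `clone_id`,
#'   `patient_id`, `arm`, `day`, `weight`.
#' @export
compute_weights <- function(models, clones, stabilize = FALSE,
                            prob_floor = 1e-10) {
  grace <- attr(clones, "grace_days") %||% 5L
  n <- nrow(clones)
  fup <- clones$followup_end
  rows <- rep(seq_len(n), fup + 1L)
  day <- sequence(fup + 1L) - 1L
  weight <- numeric(length(rows))
  for (arm in c("treated", "control")) {
    model <- models[[arm]]
    if (is.null(model))
      stopf("configuration error: missing censoring model for arm '%s'", arm)
    in_arm <- clones$arm[rows] == arm
    Z <- model_covariate_matrix(model, clones)[rows[in_arm], , drop = FALSE]
    lp <- drop(Z %*% model$coefficients)
    lam <- baseline_cumhaz_at(model, pmin(day[in_arm], grace))
    s <- exp(-lam * exp(lp))
    if (any(s < prob_floor)) {
      bad <- unique(clones$clone_id[rows[in_arm][s < prob_floor]])
      stopf(paste("weight error: uncensored probability below %g for clone(s)",
                  "%s; consider truncate_weights()"),
            prob_floor, paste(head(bad, 5), collapse = ", "))
    }
    w <- 1 / s
    if (stabilize) {
      null_model <- fit_null_censoring_model(clones[clones$arm == arm, , drop = FALSE],
                                             grace)
      w <- w * exp(-baseline_cumhaz_at(null_model, pmin(day[in_arm], grace)))
    }
    weight[in_arm] <- w
  }
  out <- data.frame(clone_id = clones$clone_id[rows],
                    patient_id = clones$patient_id[rows],
                    arm = clones$arm[rows], day = day, weight = weight)
  attr(out, "grace_days") <- grace
  attr(out, "stabilized") <- stabilize
  class(out) <- c("ccw_weights", "data.frame")
  out
}

# Marginal (covariate-free) censoring model: Nelson-Aalen of the censoring
# process, used as the stabilization numerator.
fit_null_censoring_model <- function(clones, grace) {
  cp <- censoring_process_times(clones, grace)
  times <- sort(unique(cp$time[cp$status == 1L]))
  cumhaz <- cumsum(vapply(times, function(u)
    sum(cp$status == 1L & cp$time == u) / sum(cp$time >= u), numeric(1)))
  structure(list(arm = unique(clones$arm), degenerate = length(times) == 0L,
                 coefficients = numeric(0), grace_days = grace,
                 baseline = data.frame(time = times, cumhaz = cumhaz)),
            class = "censoring_model")
}

#' Truncate extreme weights at a per-arm quantile
#'
#' @param table a [compute_weights()] table.
#' @param upper_quantile quantile in (0.5, 1]; weights above the per-arm
#'   empirical quantile are capped at it. `1` is the identity.
#' @return the table with capped weights.
#' @export
truncate_weights <- function(table, upper_quantile) {
  if (length(upper_quantile) != 1L || is.na(upper_quantile) ||
      upper_quantile <= 0.5 || upper_quantile > 1)
    stopf("configuration error: 'upper_quantile' must be in (0.5, 1]")
  if (upper_quantile == 1) return(table)
  for (arm in c("treated", "control")) {
    sel <- table$arm == arm
    if (!any(sel)) next
    cap <- quantile(table$weight[sel], upper_quantile, names = FALSE)
    table$weight[sel] <- pmin(table$weight[sel], cap)
  }
  table
}

# Last day (possibly half-open) on which a clone was exposed to artificial
# censoring: an absorbing event on day k precedes any day-k censoring
# (event-first ordering), so event-enders exit the censoring process at
# k - 1/2 and must not absorb a day-k baseline-hazard jump.
censor_exposure_end <- function(clones) {
  clones$followup_end - 0.5 * (clones$end_reason == "event")
}

# Per-clone weight at `day`, frozen at the clone's own censoring-exposure end
# (a clone absorbed at day k could only be censored before k).
clone_weight_at <- function(models, clones, day, stabilize = FALSE) {
  grace <- attr(clones, "grace_days") %||% 5L
  w <- numeric(nrow(clones))
  t_eff <- pmin(day, grace, censor_exposure_end(clones))
  for (arm in c("treated", "control")) {
    sel <- clones$arm == arm
    if (!any(sel)) next
    model <- models[[arm]]
    Z <- model_covariate_matrix(model, clones[sel, , drop = FALSE])
    wa <- 1 / uncensored_probability(model, Z, t_eff[sel])
    if (stabilize) {
      null_model <- fit_null_censoring_model(clones[sel, , drop = FALSE], grace)
      wa <- wa * exp(-baseline_cumhaz_at(null_model, t_eff[sel]))
    }
    w[sel] <- wa
  }
  w
}

#' Standardized mean differences between arms, unweighted and weighted
#'
#' Computes, among clones not artificially censored, the absolute
#' standardized mean difference
#' `|m_treated - m_control| / sqrt((v_treated + v_control) / 2)` for each
#' censoring-model covariate, both unweighted and using the
#' inverse-probability-of-censoring weights at `at_day`. Binary covariates
#' use the proportion-based variance `p(1-p)`.
#'
#' @param clones clone table.
#' @param weights a [compute_weights()] table or a numeric vector of
#'   per-clone weights aligned with `clones`.
#' @param covariate_names covariates to assess (wave is expanded).
#' @param at_day evaluation day; must be at least the grace period.
#' @return data.frame with columns `covariate`, `smd_unweighted`,
#'   `smd_weighted`.
#' @export
balance_smd <- function(clones, weights,
                        covariate_names = default_censoring_covariates,
                        at_day = NULL) {
  grace <- attr(clones, "grace_days") %||% 5L
  if (is.null(at_day)) at_day <- grace
  if (at_day < grace)
    stopf("configuration error: 'at_day' must be >= the grace period")
  if (is.data.frame(weights)) {
    # each clone's weight frozen at its censoring-exposure end: event-enders
    # (event-first ordering) take the day before their event
    key_day <- pmin(at_day, clones$followup_end -
                      (clones$end_reason == "event"))
    idx <- match(day_key(clones$clone_id, key_day),
                 day_key(weights$clone_id, weights$day))
    if (anyNA(idx))
      stopf("weight error: missing weight rows for some clone-days")
    weights <- weights$weight[idx]
  }
  keep <- clones$censor_indicator == 0L
  cl <- clones[keep, , drop = FALSE]
  w <- weights[keep]
  X <- build_covariate_matrix(cl, covariate_names)
  treated <- cl$arm == "treated"
  smd_one <- function(x, w) {
    stat <- function(sel) {
      m <- weighted.mean(x[sel], w[sel])
      if (all(x %in% c(0, 1))) {
        v <- m * (1 - m)
      } else {
        v <- sum(w[sel] * (x[sel] - m)^2) / (sum(w[sel]) - 1)
      }
      c(m, v)
    }
    st <- stat(treated); sc <- stat(!treated)
    pooled <- (st[2] + sc[2]) / 2
    if (pooled <= 0) {
      if (abs(st[1] - sc[1]) < 1e-12) return(0)
      return(NA_real_)  # undefined: different means, zero variance
    }
    abs(st[1] - sc[1]) / sqrt(pooled)
  }
  data.frame(
    covariate = colnames(X),
    smd_unweighted = apply(X, 2L, smd_one, w = rep(1, nrow(X))),
    smd_weighted = apply(X, 2L, smd_one, w = w),
    row.names = NULL)
}
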