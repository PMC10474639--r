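# Ordinal severity outcome and the weighted proportional-odds treatment
# effect. Categories order clinical status from best to worst, so an odds
# ratio above 1 means the treated arm's status distribution is shifted
# towards severity.

# state id -> ordinal category (1 home, 2 ward, 3 hcf, 4 icu, 5 death)
state_to_category <- c(2L, 4L, 5L, 1L, 3L)
category_labels <- c("home", "ward", "hcf", "icu", "death")

# Cumulative-logit likelihood machinery. Cutpoints are kept ordered through
# the unconstrained parametrization a = cumsum(c(theta_1, exp(theta_2..))),
# with the arm coefficient beta as the last parameter.
po_expand <- function(theta, K) {
  list(a = cumsum(c(theta[1L], exp(theta[seq_len(K - 2L) + 1L]))),
       beta = theta[K])
}

po_negll <- function(theta, y, x, w, K) {
  p <- po_expand(theta, K)
  au <- c(p$a, Inf)[y] - p$beta * x
  al <- c(-Inf, p$a)[y] - p$beta * x
  pr <- plogis(au) - plogis(al)
  if (any(pr <= 0)) return(1e10)
  -sum(w * log(pr))
}

po_neggr <- function(theta, y, x, w, K) {
  p <- po_expand(theta, K)
  au <- c(p$a, Inf)[y] - p$beta * x
  al <- c(-Inf, p$a)[y] - p$beta * x
  Fu <- plogis(au); Fl <- plogis(al)
  pr <- pmax(Fu - Fl, 1e-300)
  fu <- Fu * (1 - Fu); fl <- Fl * (1 - Fl)
  ga <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    ga[k] <- sum(w * ((y == k) * fu - (y == k + 1L) * fl) / pr)
  }
  gb <- -sum(w * x * (fu - fl) / pr)
  gt <- numeric(K)
  gt[1L] <- sum(ga)
  if (K > 2L) for (j in 2:(K - 1L))
    gt[j] <- sum(ga[j - 1 + seq_len(K - j)]) * exp(theta[j])
  gt[K] <- gb
  -gt
}

#' Ordinal clinical-severity status at an evaluation day
#'
#' Maps the state occupied at the end of `day` to the 5-point ordinal scale
#' (1 discharge home, 2 normal ward, 3 discharge to another healthcare
#' facility, 4 ICU, 5 in-hospital death); absorbing states keep their
#' category forever. Clones artificially censored on or before the
#' evaluation day are excluded — their weight mass is carried by the
#' uncensored clones through the censoring weights. The `four_level` variant
#' (intended for end-of-follow-up analyses) drops the normal-ward category
#' and refuses to proceed if any clone still occupies the ward.
#'
#' @param clones clone table.
#' @param day evaluation day.
#' @param variant `"five_level"` (default) or `"four_level"`.
#' @param weights per-clone weights at the evaluation day: a numeric vector
#'   aligned with `clones`, a [compute_weights()] table, or 1 for unit
#'   weights.
#' @return data.frame with `clone_id`, `arm`, `evaluation_day`, `category`
#'   (ordered factor) and `weight`, one row per uncensored clone.
#' @export
ordinal_status_at <- function(clones, day,
                              variant = c("five_level", "four_level"),
                              weights = 1) {
  variant <- match.arg(variant)
  horizon <- attr(clones, "admin_censor_day") %||% 45L
  if (day > horizon)
    stopf("configuration error: evaluation day %d beyond horizon %d",
          day, horizon)
  if (is.data.frame(weights)) {
    # freeze at the censoring-exposure end: event-enders exit the censoring
    # process just before their event day (event-first ordering)
    key_day <- pmin(day, clones$followup_end - (clones$end_reason == "event"))
    idx <- match(day_key(clones$clone_id, key_day),
                 day_key(weights$clone_id, weights$day))
    weights <- weights$weight[idx]
  }
  weights <- rep_len(weights, nrow(clones))
  keep <- !(clones$censor_indicator == 1L & clones$censor_day <= day)
  cl <- clones[keep, , drop = FALSE]
  st <- state_at_day(day, cl$icu_day, cl$event_day, cl$event_state)
  category <- state_to_category[st]
  if (variant == "four_level") {
    if (any(category == 2L))
      stopf(paste("outcome error: %d clone(s) still occupy the normal ward at",
                  "day %d; the four-level scale is undefined for ward",
                  "occupants - use variant = \"five_level\""),
            sum(category == 2L), day)
    lv <- c(1L, 3L, 4L, 5L)
  } else {
    lv <- 1:5
  }
  data.frame(clone_id = cl$clone_id, arm = cl$arm, evaluation_day = day,
             category = factor(category, levels = lv,
                               labels = category_labels[lv], ordered = TRUE),
             weight = weights[keep])
}

#' Weighted proportional-odds (cumulative logit) model for the arm effect
#'
#' Maximizes the weighted cumulative-logit log-likelihood
#' `sum_i w_i log( F(a_{y_i} - b x_i) - F(a_{y_i - 1} - b x_i) )` with the
#' treated-arm indicator as the single covariate; per-clone censoring weights
#' multiply the log-likelihood contributions. Categories with zero total
#' weight are merged into their neighbours (dropped) with a warning. The
#' returned `odds_ratio = exp(b)` is oriented so that values above 1 indicate
#' a shift towards severity in the treated arm.
#'
#' @param outcomes an [ordinal_status_at()] table.
#' @return Object of class `prop_odds`: `odds_ratio`, `log_or`, `se_log_or`,
#'   `cutpoints`, `categories`, `convergence`, `loglik`, `n`.
#' @export
weighted_proportional_odds <- function(outcomes) {
  if (!all(c("treated", "control") %in% outcomes$arm))
    stopf("estimation error: both arms must be represented")
  tab <- tapply(outcomes$weight, outcomes$category, sum)
  tab[is.na(tab)] <- 0
  empty <- names(tab)[tab == 0]
  if (length(empty)) {
    warning(sprintf("merging empty outcome categor%s: %s",
                    if (length(empty) > 1) "ies" else "y",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  y <- as.integer(droplevels(outcomes$category))
  K <- max(y)
  if (K < 2L) stopf("estimation error: need at least two outcome categories")
  x <- as.numeric(outcomes$arm == "treated")
  w <- outcomes$weight

  cum <- unname(cumsum(tapply(w, y, sum))[-K]) / sum(w)
  start <- c(qlogis(cum[1L]),
             if (K > 2L) log(pmax(diff(qlogis(cum)), 1e-3)),
             0)
  fit <- optim(start, po_negll, po_neggr, y = y, x = x, w = w, K = K,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0)
    stopf("estimation error: proportional-odds fit did not converge (code %d)",
          fit$convergence)
  H <- optimHess(fit$par, po_negll, po_neggr, y = y, x = x, w = w, K = K)
  se <- tryCatch(sqrt(solve(H)[K, K]), error = function(e) NA_real_)
  p <- po_expand(fit$par, K)
  res <- list(odds_ratio = exp(p$beta), log_or = p$beta, se_log_or = se,
              cutpoints = p$a,
              categories = levels(droplevels(outcomes$category)),
              merged = empty, convergence = fit$convergence,
              loglik = -fit$value, n = length(y))
  class(res) <- "prop_odds"
  res
}

#' @export
print.prop_odds <- function(x, ...) {
  cat(sprintf("Weighted proportional-odds fit (n = %d clones)\n", x$n))
  cat(sprintf("  OR (treated vs control, towards severity): %.4f\n",
              x$odds_ratio))
  if (is.finite(x$se_log_or))
    cat(sprintf("  log-OR %.4f (model SE %.4f)\n", x$log_or, x$se_log_or))
  invisible(x)
}

#' Bootstrap the full emulation pipeline for the odds-ratio interval
#'
#' Resamples original patients (before cloning) with replacement and reruns
#' the entire pipeline — eligibility, cloning and artificial censoring,
#' arm-specific censoring models, weights, ordinal outcome and the weighted
#' proportional-odds fit — on each replicate, so the interval reflects the
#' uncertainty of the weight estimation as well. The 95% interval is the
#' percentile interval of the replicate odds ratios; replicates that fail to
#' converge are dropped and counted (more than 10% failures is an error).
#'
#' @param patients cohort (pre-eligibility rows are fine; the pipeline
#'   applies the exclusion rules itself).
#' @param B number of bootstrap replicates.
#' @param seed seed for the resampling (mandatory).
#' @param evaluation_day day of the ordinal outcome (default 30).
#' @param variant ordinal scale variant, see [ordinal_status_at()].
#' @param config an [emulation_config()].
#' @param covariate_names censoring-model covariates.
#' @param truncation_quantile weight-truncation quantile (1 = none).
#' @param stabilize use stabilized weights.
#' @return Object of class `effect_estimate` with the point estimate,
#'   percentile CI, `n_bootstrap`, `n_failed` and the seed.
#' @export
bootstrap_pipeline <- function(patients, B = 1000L, seed,
                               evaluation_day = 30L,
                               variant = "five_level",
                               config = emulation_config(),
                               covariate_names = default_censoring_covariates,
                               truncation_quantile = 1,
                               stabilize = FALSE) {
  if (B < 1L) stopf("configuration error: 'B' must be >= 1")
  if (missing(seed)) stopf("configuration error: 'seed' is mandatory")
  point <- pipeline_odds_ratio(patients, config, covariate_names,
                               evaluation_day, variant, truncation_quantile,
                               stabilize)
  n <- nrow(patients)
  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), ncol = B))
  ors <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    boot <- patients[idx[, b], , drop = FALSE]
    boot$patient_id <- seq_len(n)  # resampled copies are distinct patients
    attr(boot, "admin_censor_day") <- attr(patients, "admin_censor_day")
    ors[b] <- tryCatch(
      suppressWarnings(
        pipeline_odds_ratio(boot, config, covariate_names, evaluation_day,
                            variant, truncation_quantile,
                            stabilize)$odds_ratio),
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(ors))
  if (failed > 0.1 * B)
    stopf("bootstrap error: %d of %d replicates failed", failed, B)
  ci <- quantile(ors, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  res <- list(evaluation_day = evaluation_day,
              odds_ratio = point$odds_ratio,
              ci_lower = ci[1L], ci_upper = ci[2L],
              n_bootstrap = B, n_failed = failed, seed = seed,
              variant = variant, replicates = ors)
  class(res) <- "effect_estimate"
  res
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "Day-%d weighted proportional odds ratio: %.3f (95%% CI %.3f-%.3f)\n",
    x$evaluation_day, x$odds_ratio, x$ci_lower, x$ci_upper))
  cat(sprintf("  bootstrap: B = %d (%d failed), seed = %d, scale = %s\n",
              x$n_bootstrap, x$n_failed, x$seed, x$variant))
  invisible(x)
}
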