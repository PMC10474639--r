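test_that("censoring Cox fit matches brute-force partial-likelihood maximization", {
  toy <- load_toy_clones()
  for (ties in c("breslow", "efron")) {
    m <- fit_censoring_model(toy, covariate_names = "sex", ties = ties)
    cp <- ccwmsm:::censoring_process_times(toy, 5)
    ref <- oracle_cox_fit(cp$time, cp$status, toy$sex, ties = ties)
    expect_equal(unname(m$coefficients), ref, tolerance = 1e-4)
  }
})

test_that("the Breslow/Efron baseline matches survival::basehaz on a full fit", {
  coh <- generate_cohort(sim_config(500, seed = 5))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  for (arm in c("treated", "control")) {
    cl <- clones[clones$arm == arm, ]
    attr(cl, "grace_days") <- 5L
    m <- fit_censoring_model(cl)
    X <- build_covariate_matrix(cl)
    cp <- ccwmsm:::censoring_process_times(cl, 5)
    ref <- survival::coxph(survival::Surv(cp$time, cp$status) ~ X,
                           ties = "efron")
    bh <- survival::basehaz(ref, centered = FALSE)
    expect_equal(unname(m$coefficients), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(m$baseline$cumhaz,
                 bh$hazard[match(m$baseline$time, bh$time)],
                 tolerance = 1e-10)
  }
})

test_that("constant covariates give a null model with Nelson-Aalen baseline", {
  toy <- load_toy_clones()
  toy$sex <- 1
  m <- fit_censoring_model(toy, covariate_names = "sex")
  expect_equal(unname(m$coefficients), 0)
  # Nelson-Aalen of the censoring process, by hand over censor days
  cp <- ccwmsm:::censoring_process_times(toy, 5)
  na_ref <- cumsum(sapply(sort(unique(cp$time[cp$status == 1])), function(u)
    sum(cp$status == 1 & cp$time == u) / sum(cp$time >= u)))
  expect_equal(m$baseline$cumhaz, na_ref)
})

test_that("an arm without artificial censoring is flagged degenerate", {
  toy <- load_toy_clones()
  toy$censor_indicator <- 0L
  toy$censor_day <- NA_integer_
  toy$end_reason[toy$end_reason == "artificial_censor"] <- "administrative"
  toy$followup_end[toy$end_reason == "administrative"] <- 45L
  m <- fit_censoring_model(toy, covariate_names = "sex")
  expect_true(m$degenerate)
  expect_equal(uncensored_probability(m, matrix(1), 5), 1)
})

test_that("uncensored probabilities follow the Breslow-exponential form", {
  model <- structure(list(arm = "control", degenerate = FALSE,
                          coefficients = c(x = 0), grace_days = 5L,
                          baseline = data.frame(time = 3, cumhaz = 0.2)),
                     class = "censoring_model")
  expect_equal(uncensored_probability(model, matrix(1), 0), 1)
  expect_equal(uncensored_probability(model, matrix(1), 3), exp(-0.2))
  model$coefficients <- c(x = 1)
  model$baseline <- data.frame(time = 5, cumhaz = 0.5)
  expect_equal(uncensored_probability(model, matrix(log(2)), 5), exp(-1))
  expect_equal(uncensored_probability(model, matrix(log(2)), 45), exp(-1))
  expect_error(uncensored_probability(model, matrix(c(1, 2), 1), 5),
               "length")
})

test_that("weight tables satisfy the structural invariants", {
  coh <- generate_cohort(sim_config(400, seed = 8))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  models <- fit_both_arms(clones)
  wt <- compute_weights(models, clones)
  expect_true(all(wt$weight[wt$day == 0] == 1))
  expect_true(all(wt$weight >= 1))
  # nondecreasing within clone, constant after the grace period
  ord <- order(wt$clone_id, wt$day)
  w <- wt$weight[ord]; id <- wt$clone_id[ord]; d <- wt$day[ord]
  same <- id[-1] == id[-length(id)]
  expect_true(all(diff(w)[same] >= -1e-12))
  expect_true(all(abs(diff(w)[same & d[-1] > 5]) < 1e-12))
  # treated-arm weights can change at the grace boundary only
  tr <- wt$arm == "treated" & wt$day < 5
  expect_true(all(wt$weight[tr] == 1))
})

test_that("weights are mean-preserving over the censoring selection", {
  coh <- generate_cohort(sim_config(4000, seed = 18))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  models <- fit_both_arms(clones)
  w <- ccwmsm:::clone_weight_at(models, clones, 45)
  for (arm in c("treated", "control")) {
    sel <- clones$arm == arm
    unc <- sel & clones$censor_indicator == 0
    expect_lt(abs(sum(w[unc]) / sum(sel) - 1), 0.06)
  }
})

test_that("stabilized weights start at 1 and stay constant after grace", {
  coh <- generate_cohort(sim_config(300, seed = 9))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  wt <- compute_weights(fit_both_arms(clones), clones, stabilize = TRUE)
  expect_true(all(wt$weight[wt$day == 0] == 1))
  ord <- order(wt$clone_id, wt$day)
  w <- wt$weight[ord]; id <- wt$clone_id[ord]; d <- wt$day[ord]
  same <- id[-1] == id[-length(id)]
  expect_true(all(abs(diff(w)[same & d[-1] > 5]) < 1e-12))
})

test_that("truncation caps at the per-arm empirical quantile", {
  tab <- data.frame(clone_id = 1:4, patient_id = 1:4, arm = "control",
                    day = 5L, weight = c(1, 1, 2, 10))
  out <- truncate_weights(tab, 0.75)
  cap <- quantile(c(1, 1, 2, 10), 0.75, names = FALSE)
  expect_equal(out$weight, pmin(c(1, 1, 2, 10), cap))
  expect_identical(truncate_weights(tab, 1), tab)
  tab2 <- tab; tab2$weight <- rep(2, 4)
  expect_equal(truncate_weights(tab2, 0.8)$weight, rep(2, 4))
  expect_error(truncate_weights(tab, 0.4), "upper_quantile")
})

test_that("standardized mean differences follow the pooled-variance formula", {
  cl <- data.frame(clone_id = 1:8, patient_id = 1:8,
                   arm = rep(c("treated", "control"), each = 4),
                   censor_indicator = 0L, followup_end = 45L,
                   end_reason = "administrative",
                   age = c(1.5, 0.5, 2.5, -0.5, 0.8, -0.2, 1.8, -1.2),
                   sex = c(1, 0, 1, 0, 1, 0, 1, 0),
                   charlson_ge2 = 0, crp = 80, ldh = 300,
                   log_ddimer = log(600), lymphocytes = 1000, wave = 1L)
  attr(cl, "grace_days") <- 5L
  b <- balance_smd(cl, weights = rep(1, 8), covariate_names = c("age", "sex"))
  # means 1 vs 0.3, variances both 5/3: SMD = 0.7 / sqrt(5/3)
  expect_equal(b$smd_unweighted[b$covariate == "age"], 0.7 / sqrt(5 / 3))
  expect_equal(b$smd_weighted[b$covariate == "age"],
               b$smd_unweighted[b$covariate == "age"])
  # identical binary distribution: zero SMD
  expect_equal(b$smd_unweighted[b$covariate == "sex"], 0)
  # identical arms by construction (cloning both arms from every patient)
  coh <- generate_cohort(sim_config(200, seed = 10))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  clones$censor_indicator <- 0L
  b2 <- balance_smd(clones, weights = rep(1, nrow(clones)))
  expect_true(all(b2$smd_unweighted < 1e-12))
  expect_error(balance_smd(clones, rep(1, nrow(clones)), at_day = 2),
               "at_day")
})

test_that("weighting restores covariate balance between the arms", {
  coh <- generate_cohort(sim_config(2000, seed = 3))
  fit <- ccw_emulate(coh)
  expect_gt(max(fit$balance$smd_unweighted), 0.1)  # confounding is real
  expect_lt(max(fit$balance$smd_weighted), 0.1)
})
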