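# The simulator is first-class code: these tests pin its distributions and
# the determinism guarantees the rest of the pipeline relies on.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(-1, seed = 1), "n_patients")
  expect_error(sim_config(10, seed = 1,
                          covariate_params = list(sex_prob = 1.4)),
               "sex_prob")
  expect_error(sim_config(10, seed = 1,
                          ineligible_fractions = c(readmission = -0.1)),
               "ineligible_fractions")
  hs <- ccwmsm:::default_hazard_spec()
  hs$transitions <- hs$transitions[-1, ]
  expect_error(sim_config(10, seed = 1, hazard_spec = hs),
               "allowed transition set")
  hs2 <- ccwmsm:::default_hazard_spec()
  hs2$transitions$base_prob <- rep(0.3, 7)
  expect_error(sim_config(10, seed = 1, hazard_spec = hs2),
               "exit probability")
})

test_that("degenerate sizes and determinism behave as contracted", {
  expect_equal(nrow(generate_cohort(sim_config(0, seed = 1))), 0)
  a <- generate_cohort(sim_config(150, seed = 42))
  b <- generate_cohort(sim_config(150, seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(sim_config(150, seed = 43))
  expect_false(identical(a, c))
})

test_that("covariates follow the configured distributions (LLN)", {
  coh <- generate_cohort(sim_config(10000, seed = 7))
  expect_lt(abs(mean(coh$age) - 65), 3 * 12 / sqrt(10000) + 0.1)  # truncation at 18 is negligible
  expect_lt(abs(mean(coh$sex) - 0.6), 0.02)
  expect_lt(abs(mean(coh$log_ddimer) - log(600)), 0.04)
})

test_that("treatment initiation follows the daily logistic model", {
  cfg0 <- sim_config(200, seed = 1, initiation_coefs = c(
    intercept = -40, day = 0, z_age = 0, sex = 0, charlson_ge2 = 0,
    z_crp = 0, z_ldh = 0, z_log_ddimer = 0, z_lymphocytes = 0,
    wave2 = 0, wave3 = 0))
  cov <- ccwmsm:::draw_covariates(200, cfg0)
  expect_true(all(is.na(simulate_treatment_initiation(cov, cfg0, seed = 1))))

  cfg1 <- sim_config(200, seed = 1, initiation_coefs = c(intercept = 40))
  expect_true(all(simulate_treatment_initiation(cov, cfg1, seed = 1) == 0))

  # daily probability 0.2 and no covariate dependence: the fraction starting
  # within the 6-day window {0..5} follows the geometric closed form
  cfgg <- sim_config(10000, seed = 1, initiation_coefs = c(
    intercept = qlogis(0.2), day = 0, z_age = 0, sex = 0, charlson_ge2 = 0,
    z_crp = 0, z_ldh = 0, z_log_ddimer = 0, z_lymphocytes = 0,
    wave2 = 0, wave3 = 0))
  cov <- ccwmsm:::draw_covariates(10000, cfgg)
  td <- simulate_treatment_initiation(cov, cfgg, seed = 5)
  p6 <- 1 - 0.8^6
  expect_lt(abs(mean(!is.na(td) & td <= 5) - p6),
            4 * sqrt(p6 * (1 - p6) / 10000))
})

zero_hazards <- function() {
  hs <- ccwmsm:::default_hazard_spec()
  hs$transitions$base_prob <- rep(0, 7)
  hs$covariate_loghr[] <- 0
  hs
}

test_that("trajectories obey null, certain and geometric hazard cases", {
  cfg <- sim_config(60, seed = 2, hazard_spec = zero_hazards())
  cov <- ccwmsm:::draw_covariates(60, cfg)
  tr <- simulate_trajectory(cov, NA_integer_, cfg, seed = 3)
  expect_true(all(is.na(tr$event_day)) && all(is.na(tr$icu_day)))
  expect_true(all(tr$history == "0:1"))

  hs <- zero_hazards()
  hs$transitions$base_prob[hs$transitions$from == 1 &
                             hs$transitions$to == 3] <- 1 - 1e-9
  cfg2 <- sim_config(60, seed = 2, hazard_spec = hs)
  tr2 <- simulate_trajectory(cov, NA_integer_, cfg2, seed = 3)
  expect_true(all(tr2$event_day == 1 & tr2$event_state == 3))

  hs$transitions$base_prob[hs$transitions$from == 1 &
                             hs$transitions$to == 3] <- 0.1
  cfg3 <- sim_config(10000, seed = 2, hazard_spec = hs)
  cov3 <- ccwmsm:::draw_covariates(10000, cfg3)
  tr3 <- simulate_trajectory(cov3, NA_integer_, cfg3, seed = 4)
  p30 <- 1 - 0.9^30
  expect_lt(abs(mean(!is.na(tr3$event_day) & tr3$event_day <= 30) - p30),
            4 * sqrt(p30 * (1 - p30) / 10000))
})

test_that("hazards that sum past 1 raise a rescaling error", {
  hs <- ccwmsm:::default_hazard_spec()
  hs$covariate_loghr[, "z_age"] <- 8  # explodes for any above-average age
  cfg <- sim_config(200, seed = 3, hazard_spec = hs)
  cov <- ccwmsm:::draw_covariates(200, cfg)
  expect_error(simulate_trajectory(cov, NA_integer_, cfg, seed = 1),
               "rescale")
})

test_that("occupation oracle rows are exact probability vectors", {
  cfg <- sim_config(10, seed = 1)
  occ <- occupation_oracle(cfg, "never", n_mc = 2000, seed = 11)
  expect_equal(unname(rowSums(occ)), rep(1, 46), tolerance = 1e-12)
  expect_true(all(occ >= 0))
  expect_error(occupation_oracle(cfg, "never", n_mc = 0, seed = 1), "n_mc")

  cfg0 <- sim_config(10, seed = 1, hazard_spec = zero_hazards())
  occ0 <- occupation_oracle(cfg0, "never", n_mc = 500, seed = 11)
  expect_equal(unname(occ0[, "ward"]), rep(1, 46))
})

test_that("two-state oracle matches the geometric closed form", {
  hs <- zero_hazards()
  hs$transitions$base_prob[hs$transitions$from == 1 &
                             hs$transitions$to == 3] <- 0.1
  cfg <- sim_config(10, seed = 1, hazard_spec = hs)
  occ <- occupation_oracle(cfg, "never", n_mc = 50000, seed = 21)
  for (t in c(5, 10, 30)) {
    p <- 1 - 0.9^t
    expect_lt(abs(occ[t + 1, "death"] - p), 4 * sqrt(p * (1 - p) / 50000))
  }
})

test_that("null treatment effect makes policies indistinguishable", {
  cfg <- sim_config(10, seed = 1)  # default treatment log-HRs are zero
  a <- occupation_oracle(cfg, "never", n_mc = 30000, seed = 31)
  b <- occupation_oracle(cfg, 0, n_mc = 30000, seed = 32)
  expect_lt(max(abs(a["day30", ] - b["day30", ])), 0.015)
})

test_that("with null covariate effects trajectories are exchangeable across strata", {
  hs <- ccwmsm:::default_hazard_spec()
  hs$covariate_loghr[] <- 0
  cfg <- sim_config(10000, seed = 9, hazard_spec = hs)
  coh <- generate_cohort(cfg)
  state30 <- ccwmsm:::state_at_day(30, coh$icu_day, coh$event_day,
                                   coh$event_state)
  tab <- table(coh$charlson_ge2, state30)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)
})
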