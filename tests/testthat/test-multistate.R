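test_that("long format rows enumerate clone-days by out-degree", {
  # clone censored day 3 from ward: 3 days x 4 destinations, all status 0
  cl <- load_toy_clones()[12, ]
  attr(cl, "grace_days") <- 5L
  long <- build_long_format(cl, unit_weight_table(cl), horizon = 45)
  expect_equal(nrow(long), 12)
  expect_true(all(long$status == 0))
  expect_true(all(long$from == 1))

  # ward -> icu day 2, icu -> death day 8 (toy clone 8):
  # 1 day in ward (4 dests) + 6 days in icu (3 dests)
  cl8 <- load_toy_clones()[8, ]
  attr(cl8, "grace_days") <- 5L
  long8 <- build_long_format(cl8, unit_weight_table(cl8), horizon = 45)
  expect_equal(nrow(long8), 2 * 4 + 6 * 3)
  hits <- long8[long8$status == 1, c("day", "from", "to")]
  expect_equal(hits[order(hits$day), ],
               data.frame(day = c(2L, 8L), from = c(1L, 2L), to = c(2L, 3L)),
               ignore_attr = TRUE)

  # 3-clone toy set, counted by hand
  cl3 <- load_toy_clones()[c(4, 5, 7), ]
  attr(cl3, "grace_days") <- 5L
  long3 <- build_long_format(cl3, unit_weight_table(cl3), horizon = 45)
  # clone 4: 3 ward days; clone 5: 1 ward day; clone 7: 6 ward + 39 icu days
  expect_equal(nrow(long3), (3 + 1 + 6) * 4 + 39 * 3)

  expect_error(build_long_format(cl8, unit_weight_table(cl8)[-3, ],
                                 horizon = 45), "missing weight")
})

test_that("weighted Nelson-Aalen evaluates increments as dN^W / Y^W", {
  # three clones in ward at day 1 with weights 1, 2, 1; the weight-2 clone
  # dies on day 1: increment 2 / 4
  cl <- data.frame(patient_id = 1:3, arm = "control",
                   censor_day = NA_integer_, censor_indicator = 0L,
                   followup_end = c(2L, 1L, 2L),
                   end_reason = c("administrative", "event", "administrative"),
                   terminal_state = c(1L, 3L, 1L),
                   icu_day = NA_integer_,
                   event_day = c(NA, 1L, NA), event_state = c(NA, 3L, NA),
                   clone_id = 1:3)
  wt <- unit_weight_table(cl)
  wt$weight[wt$clone_id == 2] <- 2
  long <- build_long_format(cl, wt, horizon = 2)
  ch <- weighted_nelson_aalen(long)
  expect_equal(ch$transitions[["1->3"]]$increment, 0.5)
  expect_equal(ch$transitions[["1->3"]]$day, 1L)
  expect_equal(nrow(ch$transitions[["1->2"]]), 0)
})

test_that("unit weights reduce to the standard Nelson-Aalen estimator", {
  coh <- generate_cohort(sim_config(300, seed = 14))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  cl <- clones[clones$arm == "control" & is.na(clones$icu_day), ]
  # single-transition view: ward -> death, other exits treated as censoring
  cl <- cl[cl$end_reason != "event" | cl$event_state == 3, ]
  attr(cl, "grace_days") <- 5L
  long <- build_long_format(cl, unit_weight_table(cl), horizon = 45)
  ch <- weighted_nelson_aalen(long)
  sf <- survival::survfit(survival::Surv(cl$followup_end,
                                         cl$end_reason == "event") ~ 1)
  ref <- sf$cumhaz[sf$n.event > 0]
  expect_equal(ch$transitions[["1->3"]]$cumhaz, ref, tolerance = 1e-12)
})

test_that("Aalen-Johansen special cases match closed forms and survival", {
  # no events: identity for all t
  cl <- load_toy_clones()[10, ]
  attr(cl, "grace_days") <- 5L
  ch <- weighted_nelson_aalen(build_long_format(cl, unit_weight_table(cl),
                                                horizon = 45))
  pt <- aalen_johansen(ch)
  expect_equal(pt$P[, , 46], diag(5), ignore_attr = TRUE)

  # two clones, one death at day 1: P11(0,1) = 0.5
  cl2 <- data.frame(patient_id = 1:2, arm = "control",
                    censor_day = NA_integer_, censor_indicator = 0L,
                    followup_end = c(1L, 45L),
                    end_reason = c("event", "administrative"),
                    terminal_state = c(3L, 1L), icu_day = NA_integer_,
                    event_day = c(1L, NA), event_state = c(3L, NA),
                    clone_id = 1:2)
  ch2 <- weighted_nelson_aalen(build_long_format(cl2, unit_weight_table(cl2),
                                                 horizon = 45))
  pt2 <- aalen_johansen(ch2)
  expect_equal(pt2$P[1, 1, 2], 0.5)

  # two-state case equals 1 - Kaplan-Meier on the day grid
  coh <- generate_cohort(sim_config(400, seed = 15))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  cl3 <- clones[clones$arm == "control" & is.na(clones$icu_day), ]
  cl3 <- cl3[cl3$end_reason != "event" | cl3$event_state == 3, ]
  attr(cl3, "grace_days") <- 5L
  ch3 <- weighted_nelson_aalen(build_long_format(cl3, unit_weight_table(cl3),
                                                 horizon = 45))
  occ <- state_occupation(aalen_johansen(ch3))
  km <- survival::survfit(survival::Surv(cl3$followup_end,
                                         cl3$end_reason == "event") ~ 1)
  for (d in c(5, 15, 30, 45)) {
    s_km <- summary(km, times = d)$surv
    expect_equal(occ[d + 1, "death"], 1 - s_km, tolerance = 1e-12)
  }
})

test_that("competing-risks absorbing probabilities equal classical CIFs", {
  skip_if_not_installed("cmprsk")
  coh <- generate_cohort(sim_config(500, seed = 16))
  clones <- clone_and_censor(apply_eligibility(coh)$eligible)
  cl <- clones[clones$arm == "control" & is.na(clones$icu_day), ]
  attr(cl, "grace_days") <- 5L
  ch <- weighted_nelson_aalen(build_long_format(cl, unit_weight_table(cl),
                                                horizon = 45))
  occ <- state_occupation(aalen_johansen(ch))
  fst <- ifelse(cl$end_reason == "event", cl$event_state, 0)
  ci <- cmprsk::cuminc(cl$followup_end, fst, cencode = 0)
  for (state in 3:5) {
    est <- cmprsk::timepoints(ci, times = c(15, 30))$est
    row <- grep(paste0(" ", state, "$"), rownames(est))
    expect_equal(unname(occ[c(16, 31), colnames(occ)[state]]),
                 unname(est[row, ]), tolerance = 1e-10)
  }
})

test_that("transition-probability matrices are row-stochastic on random cohorts", {
  for (s in 1:4) {
    coh <- generate_cohort(sim_config(250, seed = 600 + s))
    fit <- ccw_emulate(coh)
    for (arm in c("treated", "control")) {
      P <- fit$probtrans[[arm]]$P
      sums <- apply(P, 3, rowSums)
      expect_lt(max(abs(sums - 1)), 1e-10)
      expect_true(all(P >= -1e-15 & P <= 1 + 1e-12))
      occ <- fit$occupation[[arm]]
      for (state in c("death", "home", "hcf"))
        expect_true(all(diff(occ[, state]) >= -1e-12))
    }
  }
})

test_that("a total daily increment above 1 is reported as an error", {
  ch <- weighted_nelson_aalen(
    build_long_format(load_toy_clones(), unit_weight_table(load_toy_clones()),
                      horizon = 45))
  ch$transitions[["1->3"]] <- data.frame(day = 2L, n_events_w = 9,
                                         n_risk_w = 10, increment = 0.9,
                                         cumhaz = 0.9)
  ch$transitions[["1->4"]] <- data.frame(day = 2L, n_events_w = 9,
                                         n_risk_w = 10, increment = 0.9,
                                         cumhaz = 0.9)
  expect_error(aalen_johansen(ch), "day 2")
})

test_that("observed transitions outside the allowed set are rejected", {
  cl <- load_toy_clones()[8, ]
  cl$icu_day <- NA_integer_  # death day 8 now appears as ward -> death
  attr(cl, "grace_days") <- 5L
  ts <- transition_structure(cbind(c(1, 1, 1, 2, 2, 2, 1),
                                   c(2, 4, 5, 3, 4, 5, 3)))
  ts2 <- transition_structure(cbind(c(1, 1, 1, 2, 2, 2),
                                    c(2, 4, 5, 3, 4, 5)))
  expect_silent(build_long_format(cl, unit_weight_table(cl), ts, horizon = 45))
  expect_error(build_long_format(cl, unit_weight_table(cl), ts2,
                                 horizon = 45))
})
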