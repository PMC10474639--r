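---
title: "Emulating a target trial with clone-censor-weight and multi-state estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a target trial with clone-censor-weight and multi-state estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccwmsm)
```

## The problem this package addresses

Observational cohorts of hospitalized patients are routinely used to ask
whether an early-administered treatment changes the clinical course. Three
biases make naive analyses of such data unreliable:

* **Immortal time bias** — if exposure is defined by whether a patient
  *ever* received the treatment, treated patients are guaranteed to have
  survived (and stayed in hospital) until their dose, inflating their
  apparent survival.
* **Confounding by indication** — treatment decisions depend on severity
  markers, so treated and untreated groups differ at baseline.
* **Competing risks** — death, discharge home and discharge to another
  healthcare facility (HCF) compete; censoring discharges as if they were
  uninformative overestimates death risks.

`ccwmsm` implements a complete analysis pipeline for this situation:
target-trial emulation by the clone-censor-weight (CCW) technique with a
treatment-initiation grace period, inverse probability of artificial
censoring weighting (IPCW), weighted non-parametric multi-state estimation
(Nelson-Aalen cumulative transition hazards, Aalen-Johansen transition
probabilities), and a weighted proportional-odds summary of the treatment
effect on an ordinal severity scale, with a bootstrap over the whole
pipeline for confidence intervals. Because real hospital records of this
kind are typically sensitive and cannot be shipped, the package includes a
discrete-time cohort simulator that reproduces the relevant structure and
serves as its test bed, together with a Monte-Carlo oracle for ground-truth
state-occupation probabilities.

## The emulated trial

Each eligible patient enters follow-up at hospital admission (day 0) in the
normal ward. The two strategies compared are "initiate the single-dose
treatment within the first `grace_days = 5` days" versus "do not initiate
within that window". Since a patient's strategy assignment cannot be known
at day 0, *every* patient is cloned into both arms ([clone_and_censor()]):

* the **control clone** is artificially censored on the day treatment
  starts, if that happens within the grace period;
* the **treated clone** is artificially censored at the end of the grace
  period if treatment has not started by then (and the patient is still in
  hospital);
* a patient who reaches an absorbing state within the grace period before
  treatment ends both clones at the event — their protocol adherence is
  vacuously complete;
* treatment initiated *after* the grace period classifies the patient as
  control; the control clone is not censored later for it.

Follow-up ends at the absorbing event or administratively at
`admin_censor_day = 45` days.

Two tie conventions matter on a daily grid and are fixed as follows. A dose
recorded on the same day as an outcome event is taken to have been
administered first (a dose is given to a live, hospitalized patient), so
the control clone is censored and the treated clone keeps the event. A
day-0 dose censors the control clone at day 1, the entry to the first risk
interval — day values below 1 are not representable in the censoring
model's time axis.

## Censoring weights

Artificial censoring depends on covariates (through the confounded
treatment decision), so the censored clones are not exchangeable with the
uncensored ones. The selection is undone by IPCW. For each arm separately,
a Cox model for the time to *artificial censoring* is fitted on the clones
([fit_censoring_model()]), with the baseline covariates as predictors: age,
sex, the dichotomized Charlson comorbidity index, C-reactive protein,
lactate dehydrogenase, log D-dimer, lymphocyte count and the pandemic-wave
category. The conditional probability of remaining uncensored uses the
Breslow-form survival function

    S_C(t | Z) = exp( -Lambda_0C(min(t, grace)) * exp(beta_C' Z) )

and the unstabilized weight of clone *i* at day *t* is
`W_i(t) = 1 / S_C(min(t, grace) | Z_i)` ([compute_weights()]). Weights are
1 at day 0, nondecreasing, and constant after the grace period. In the
treated arm all censoring happens at grace end, so treated-arm weights are
exactly 1 before day 5 and jump once.

Numerical conventions, all covered by tests:

* **Within-day ordering.** Outcome events precede censoring within a day:
  a clone whose event occurs on day *k* leaves the censoring risk set at
  *k − 1/2*, and its own frozen weight is evaluated just *before* day *k*,
  so it never absorbs a censoring-hazard jump it was not exposed to.
* **Tie handling.** The partial likelihood uses Efron's method. This is a
  deliberate choice: the grace-period design puts *all* treated-arm
  censorings in one tie at day 5 (often half the arm), and under such a tie
  mass Breslow's approximation attenuates the coefficients enough to defeat
  the covariate balance the weights exist to restore; Efron's method is
  accurate there. `ties = "breslow"` remains available, and the baseline
  cumulative hazard always matches the tie method of the fit.
* **Risk-set weighting.** Whether the estimators should use left- or
  right-continuous weights on the daily grid is underdetermined; the
  package fixes the left-continuous carry: the weight attached to the risk
  interval `(t-1, t]` is `W_i(t-1)`. A clone's own censoring day therefore
  never inflates its final contribution.
* **Extreme weights.** The continuous markers are heavy-tailed, and single
  clones can draw very large weights. Truncation at a per-arm quantile is
  available for such cases ([truncate_weights()], e.g.
  `truncation_quantile = 0.99`) but is off by default: capping removes
  exactly the large corrections that belong to rarely-treated healthy
  patients, and in the package's own validation runs untruncated weights
  gave both better covariate balance and less biased occupation curves.
  Stabilized weights (arm-specific marginal uncensored probability in the
  numerator) are available via `stabilize = TRUE`.

Balance is assessed with standardized mean differences before and after
weighting ([balance_smd()]), among clones not artificially censored, using
proportion-based variances for binary covariates; values below 0.1
conventionally indicate balance.

## The multi-state model

Five states: 1 normal ward, 2 ICU, 3 in-hospital death, 4 discharge home,
5 discharge to another HCF; seven forward-only transitions (four ward
exits, three ICU exits), with death and the two discharge states absorbing
([transition_structure()]). The three ICU exits mirror the ward's
non-recovery exits; a return transition ICU → ward is deliberately not
modelled. The clone table is expanded into a long counting-process format
with one row per clone-day at risk and allowed destination
([build_long_format()]); artificial and administrative censoring contribute
at-risk rows but never a `status = 1` row, so a transition coinciding with
a clone's censor day is not counted — with a large grace-end tie this
slightly undercounts day-5 ICU entries in the treated arm, a conservative
consequence of the convention that is documented here on purpose.

Weighted cumulative transition hazards use the weighted Nelson-Aalen
estimator `dA_lm(u) = dN^W_lm(u) / Y^W_l(u)` summed over event days
([weighted_nelson_aalen()]), and transition probabilities the weighted
Aalen-Johansen product-integral `P(s,t) = prod (I + dA(u))`
([aalen_johansen()]), with same-day transitions across clones aggregated
into one product factor. Rows of `P` are stochastic by construction; the
diagonal of a daily factor going negative (total increment above 1) raises
an error rather than being clipped. With unit weights both estimators
reduce *exactly* to their classical counterparts, which the test suite
verifies against independent implementations (`survival`, `cmprsk`). The
Markov property is assumed by the simulator but not enforced by the
estimators; read the reported curves as state-occupation probabilities
from admission ([state_occupation()]).

## The ordinal effect summary

Clinical severity at an evaluation day maps the occupied state to the
ordered scale 1 discharge home < 2 normal ward < 3 discharge to HCF <
4 ICU < 5 in-hospital death ([ordinal_status_at()]); absorbing states keep
their category forever. A weighted cumulative-logit (proportional-odds)
model with the treated-arm indicator as the only covariate is maximized
directly, each clone's log-likelihood contribution multiplied by its
censoring weight at the evaluation day ([weighted_proportional_odds()]).
The reported `OR = exp(beta)` is oriented so that values above 1 mean the
treated arm's severity distribution is shifted towards death. Confidence
intervals come from a nonparametric bootstrap over the *entire* pipeline
([bootstrap_pipeline()]): original patients (pre-cloning) are resampled
with replacement, and eligibility, cloning, censoring-model fitting,
weighting and the ordinal fit are rerun per replicate, so weight-estimation
uncertainty is inside the interval. The resampling unit is the patient, not
the clone — resampling clones would break the within-patient coupling the
cloned design creates. Percentile intervals are used as the simplest
defensible default, with 1000 replicates by default and the interval type
recorded in the output. The primary evaluation day is 30; days 20 and 45
are conventional secondary choices.

A four-level variant of the scale (dropping the normal ward) exists for
end-of-follow-up analyses. How ward occupants at day 45 should be
categorized on a four-level scale is genuinely ambiguous — with
administrative censoring some patients *are* still on the ward — so
[ordinal_status_at()] refuses with an error in that case instead of
guessing, and the five-level scale is the safe variant at any day.

## The synthetic cohort generator

[generate_cohort()] draws, per patient: age (normal, mean 65, SD 12 years,
truncated at 18), sex (60% male), Charlson index ≥ 2 (45%), C-reactive
protein (log-normal, median 80 mg/L), lactate dehydrogenase (log-normal,
median 300 U/L), D-dimer (log-normal, median 600 ng/mL, stored on the log
scale), lymphocyte count (log-normal, median 1000 ×10⁶/L) and a
three-level pandemic-wave category (45/35/20%). These medians and spreads
are typical of moderate-to-severe COVID-19 admission panels and give the
marker distributions their characteristic right skew.

Treatment initiation is a daily Bernoulli draw with logistic probability
`plogis(intercept + coefs' z + day_coef * d)`; the defaults (intercept
−2.9, day −0.15, covariate log-odds 0.1–0.35 per SD, higher for older and
more inflamed patients) give roughly a quarter of patients initiating
within the 5-day grace period and a few percent afterwards. Initiation
depends only on baseline covariates, so all confounding is time-fixed —
matching the adjustment set the analysis uses. The initiation model is
linear on the *raw* marker scale, which makes the analysis censoring models
(linear CRP, LDH, lymphocytes; logged D-dimer) correctly specified.

Trajectories follow a discrete-day competing-risks scheme: each day, a
patient in a transient state moves to destination *m* with probability
`base_prob * exp(loghr' z + trt_loghr * treated(t))`; the competing
destinations are drawn from a single categorical distribution per day, so
at most one transition happens per patient-day. Transition hazards use
log-scale marker scores, keeping daily exit probabilities bounded under the
heavy tails (a configuration whose modified exit probability still reaches
1 raises an error asking for rescaled hazards). Baseline daily
probabilities (ward: 0.024 ICU, 0.016 death, 0.026 home, 0.015 HCF; ICU:
0.045 death, 0.012 home, 0.020 HCF) put roughly a third of patients in the
death state by day 30 with a few percent still on the ward at day 45. The
treatment effect is multiplicative on each transition hazard from the
initiation day onward (inclusive — a single dose with immediate effect)
and is zero by default, the null case the validation study conditions use.
Records violating the four exclusion rules (hospital-acquired infection,
readmission, pre-admission treatment, outcome on the admission day) are
injected at small configurable rates so the eligibility stage has real work
to do.

[occupation_oracle()] simulates trajectories under a *forced* policy
(never-treat or treat-at-day-d), bypassing the confounded initiation, and
tabulates true state-occupation probabilities — the ground truth the
weighted pipeline is checked against.

What the simulator deliberately does not emulate: time-varying covariates
and time-varying confounding, vaccination status, ICU→ward recovery,
between-wave changes in standard of care, measurement error and missing
covariate values. Passing recovery tests on these cohorts therefore shows
that the pipeline removes time-fixed confounding and design-induced
selection on a forward-only Markov course — not that it is robust to
violations the simulator never produces.

## Validation design and problem sizes

The test suite checks, among others: exact reductions of the weighted
estimators to `survival`'s Nelson-Aalen/Kaplan-Meier and `cmprsk`'s
cumulative incidence curves under unit weights; a 12-clone hand fixture
whose Nelson-Aalen increments, Aalen-Johansen matrices and censoring-model
coefficients are reproduced by brute-force counting and direct optimization
of the written-out partial likelihood; covariate balance (maximum weighted
SMD ≤ 0.1 at n = 2000); recovery of true day-30 occupation probabilities
within 0.03 absolute on n = 5000 cohorts against a 200 000-trajectory
oracle, alongside a demonstration that the naive ever-treated analysis is
systematically biased under the same conditions; and 95% bootstrap
coverage of the null odds ratio across 100 cohorts of n = 1000 with
B = 200. These sizes were chosen to make Monte-Carlo error small relative
to the tolerances while keeping the default check run comfortably on one
CPU.

## Known limitations

* The Breslow-form survival `exp(-Lambda_0 e^{beta'Z})` is an
  approximation on a discrete day grid. When the per-day censoring mass is
  large — the treated arm censors about half its clones in a single day —
  the implied complementary-log-log response can under-correct the
  selection even with Efron ties, leaving a small residual severity excess
  in the treated arm's weighted risk set (visible as a percent-level
  inflation of its post-grace hazards at moderate n). Balance diagnostics
  should always be inspected; enriching the weight model's functional form
  is supported via `covariate_names`.
* Artificial censoring truncates same-day transitions (see above); with a
  large grace-end tie this undercounts day-5 ICU entries in the treated
  arm.
* The proportional-odds summary assumes a common odds ratio across
  severity cut-points; it is a convenient one-number summary, not a test
  of that assumption.
* Percentile bootstrap intervals can undercover when the replicate
  distribution is strongly skewed at small n; B = 1000 (the default) is
  recommended for reported intervals.

## A minimal run

```{r example, eval = FALSE}
coh <- generate_cohort(sim_config(n_patients = 500, seed = 42))
fit <- ccw_emulate(coh)
fit$balance                              # SMDs before/after weighting
round(fit$occupation$treated["day30", ], 3)
bootstrap_pipeline(coh, B = 1000, seed = 42)
```

The same pipeline is scriptable from a shell via the thin CLI wrapper in
`inst/cli/ccwmsm.R` (`simulate`, `estimate`, `run-all`), driven by a YAML
run configuration ([read_run_config()]).
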