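# ccwmsm

Target-trial emulation with clone-censor-weight and weighted multi-state
estimation for hospitalized cohorts.

## What it is for

Observational studies that ask "does early treatment X change the clinical
course of hospitalized patients?" face three classic biases: immortal time
(exposure defined by information from after admission), confounding by
indication (sicker patients get treated), and competing risks (death,
discharge home and discharge to another healthcare facility compete).
`ccwmsm` is an R implementation of the combined design that addresses all
three at once, aimed at biostatisticians and epidemiologists analyzing
patient-level hospital data:

1. **Clone-censor-weight emulation.** Every eligible patient is cloned into
   both protocol arms at admission (day 0). Clones are artificially
   censored when the patient's observed treatment timing deviates from
   their arm's strategy over a 5-day grace period; treatment after the
   grace period classifies a patient as control.
2. **Inverse probability of artificial censoring weights.** Arm-specific
   Cox models `lambda_C(t|Z) = lambda_0C(t) exp(beta_C' Z)` for the
   censoring hazard give each clone the weight

   `W_i(t) = 1 / S_C(min(t, grace) | Z_i)`,   `S_C(t|Z) = exp(-Lambda_0C(t) exp(beta_C' Z))`,

   restoring covariate balance between arms (checked with standardized
   mean differences).
3. **Weighted multi-state estimation** over the five-state forward model
   (ward → {ICU, death, home, HCF}, ICU → {death, home, HCF}): weighted
   Nelson-Aalen cumulative transition hazards
   `A_lm(t) = sum_u dN^W_lm(u) / Y^W_l(u)` and weighted Aalen-Johansen
   transition probabilities `P(s,t) = prod_u (I + dA(u))`, yielding
   per-arm state-occupation curves.
4. **Weighted proportional-odds effect summary** on the ordinal severity
   scale (1 home < 2 ward < 3 HCF < 4 ICU < 5 death) at day 30, with 95%
   percentile intervals from a nonparametric bootstrap that reruns the
   whole pipeline on resampled patients.

Because data of this kind are sensitive and rarely shareable, the package
ships a discrete-time synthetic cohort generator with covariate-dependent
(confounded) treatment initiation and a Monte-Carlo oracle of true
state-occupation probabilities, used throughout the test suite to verify
that the pipeline removes the biases it claims to remove.

## Worked example

```r
library(ccwmsm)

coh <- generate_cohort(sim_config(n_patients = 500, seed = 42))
fit <- ccw_emulate(coh)
print(fit)
#> Clone-censor-weight emulation
#>   eligible patients: 459 (excluded: 41)
#>   treated arm: 459 clones, 234 artificially censored
#>   control arm: 459 clones, 93 artificially censored
#>   max weighted SMD at grace end: 0.118
#>   day-30 death probability: treated 0.362, control 0.385

round(fit$occupation$control["day30", ], 3)
#>  ward   icu death  home   hcf
#> 0.028 0.049 0.385 0.300 0.237

bootstrap_pipeline(coh, B = 200, seed = 42)
#> Day-30 weighted proportional odds ratio: 0.948 (95% CI 0.690-1.281)
#>   bootstrap: B = 200 (0 failed), seed = 42, scale = five_level
```

Reading the output: 41 of 500 simulated patients violate an exclusion rule
(hospital-acquired infection, readmission, pre-admission treatment, or an
outcome on the admission day). Each of the 459 eligible patients
contributes one clone per arm; 234 treated-arm clones never start treatment
within the grace period and are censored at day 5, while 93 control-arm
clones start treatment inside the grace period and are censored on their
treatment day. After weighting, the day-30 state-occupation row says a
control-strategy patient has a 38.5% probability of having died in
hospital, 30.0% of being home, 23.7% of having been discharged to another
facility, and 4.9%/2.8% of still being in the ICU/ward. The day-30 odds
ratio of 0.95 (CI crossing 1) is consistent with the simulator's default
null treatment effect; values above 1 would indicate a shift towards
severity in the treated arm. At this sample size single weighted SMDs can
exceed the 0.1 balance threshold by sampling noise (0.118 here); the
balance criterion is met reliably at n = 2000 (see the tests).

A shell entry point wrapping the same functions lives at
`inst/cli/ccwmsm.R`:

```sh
Rscript inst/cli/ccwmsm.R run-all --n 500 --seed 42 --out-dir results/
```

## Documentation

The methods vignette
(`vignettes/clone-censor-weight-multistate.Rmd`) documents the model and
its assumptions, the tie-breaking and weighting conventions on the daily
grid, the simulator's distributions and their defaults, and known
limitations.
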