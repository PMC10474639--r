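# Run configuration and the two orchestration entry points used by the CLI
# wrapper (inst/cli/ccwmsm.R): simulate a cohort file, and run the full
# emulation + estimation bundle on a cohort file.

default_run_config <- function() {
  list(
    paths = list(cohort = "cohort.csv", output_dir = "ccwmsm-output"),
    emulation = list(grace_days = 5L, admin_censor_day = 45L),
    weights = list(stabilize = FALSE, truncation_quantile = 1),
    analysis = list(evaluation_days = c(20L, 30L), variant = "five_level",
                    n_bootstrap = 200L, seed = 1L),
    simulation = list(n_patients = 500L, seed = 1L))
}

#' Read a run configuration from YAML
#'
#' Keys mirror [default sections][run_simulate()]: `paths`, `emulation`,
#' `weights`, `analysis`, `simulation`; missing keys fall back to defaults.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (is.null(cfg$analysis$seed) || is.null(cfg$simulation$seed))
    stopf("configuration error: a seed is mandatory for every stochastic stage")
  cfg
}

write_meta <- function(dir, name, cfg, extra = list()) {
  meta <- c(list(package = "ccwmsm",
                 version = as.character(packageVersion("ccwmsm")),
                 config = cfg), extra)
  yaml::write_yaml(meta, file.path(dir, name))
}

#' Simulate a cohort file from a run configuration
#'
#' Writes the cohort CSV plus a YAML metadata sidecar (configuration echo,
#' seed, package version) next to it.
#'
#' @param config nested configuration list ([read_run_config()]) or a YAML
#'   path.
#' @return the cohort file path, invisibly.
#' @export
run_simulate <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  sim <- config$simulation
  sc <- sim_config(
    n_patients = sim$n_patients, seed = sim$seed,
    covariate_params = sim$covariate_params %||% list(),
    initiation_coefs = sim$initiation_coefs,
    hazard_spec = sim$hazard_spec,
    admin_censor_day = config$emulation$admin_censor_day,
    grace_days = config$emulation$grace_days)
  cohort <- generate_cohort(sc)
  path <- config$paths$cohort
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, path)
  write_meta(dirname(path), paste0(basename(path), ".meta.yaml"), config,
             list(stage = "simulate", n_patients = nrow(cohort)))
  message(sprintf("simulate: wrote %d patients to %s", nrow(cohort), path))
  invisible(path)
}

#' Run the full emulation and estimation bundle on a cohort file
#'
#' Reads the cohort, runs [ccw_emulate()] and [bootstrap_pipeline()] at the
#' configured evaluation days, and writes the report bundle: exclusion log,
#' clone table, weight table, balance report, per-arm cumulative hazards,
#' state-occupation probabilities and effect estimates, plus a YAML metadata
#' sidecar carrying the seed and package version.
#'
#' @param config nested configuration list or YAML path.
#' @return list with the [ccw_emulate()] result and the effect estimates,
#'   invisibly.
#' @export
run_emulation <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  # every bundle file carries the run seed and package version as a leading
  # comment line (read back with comment.char = "#")
  out_csv <- function(df, name) {
    path <- file.path(out, name)
    writeLines(sprintf("# ccwmsm %s seed=%d",
                       as.character(packageVersion("ccwmsm")),
                       as.integer(config$analysis$seed)), path)
    suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                                 row.names = FALSE, col.names = TRUE,
                                 quote = FALSE, na = ""))
  }
  cohort <- stage("read_cohort", read_cohort(
    config$paths$cohort, config$emulation$admin_censor_day))
  message(sprintf("read_cohort: %d patients", nrow(cohort)))
  emu_cfg <- emulation_config(config$emulation$grace_days,
                              config$emulation$admin_censor_day)
  fit <- stage("emulate_estimate", ccw_emulate(
    cohort, emu_cfg,
    truncation_quantile = config$weights$truncation_quantile,
    stabilize = config$weights$stabilize))
  message(sprintf("emulate: %d eligible, %d clones, %d artificially censored",
                  nrow(fit$eligible), nrow(fit$clones),
                  sum(fit$clones$censor_indicator)))
  out_csv(fit$exclusions, "exclusions.csv")
  clone_cols <- c("patient_id", "arm", "censor_day", "censor_indicator",
                  "followup_end", "end_reason", "terminal_state",
                  covariate_columns(fit$clones))
  out_csv(as.data.frame(fit$clones)[, clone_cols], "clones.csv")
  out_csv(as.data.frame(fit$weights)[, c("patient_id", "arm", "day",
                                         "weight")], "weights.csv")
  out_csv(fit$balance, "balance.csv")
  for (arm in c("treated", "control")) {
    out_csv(as.data.frame(fit$cumhaz[[arm]]), sprintf("cumhaz_%s.csv", arm))
  }
  out_csv(occupation_long(fit$occupation), "occupation.csv")

  an <- config$analysis
  effects <- stage("effects", {
    lapply(an$evaluation_days, function(d)
      bootstrap_pipeline(cohort, B = an$n_bootstrap, seed = an$seed,
                         evaluation_day = d, variant = an$variant,
                         config = emu_cfg,
                         truncation_quantile = config$weights$truncation_quantile,
                         stabilize = config$weights$stabilize))
  })
  eff_df <- do.call(rbind, lapply(effects, function(e)
    data.frame(day = e$evaluation_day, odds_ratio = e$odds_ratio,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper,
               n_bootstrap = e$n_bootstrap, n_failed = e$n_failed,
               seed = e$seed)))
  out_csv(eff_df, "effects.csv")
  writeLines(c("Weighted proportional-odds treatment effect",
               sprintf("day %d: OR %.3f (95%% CI %.3f-%.3f), B=%d, seed=%d, dropped=%d",
                       eff_df$day, eff_df$odds_ratio, eff_df$ci_lower,
                       eff_df$ci_upper, eff_df$n_bootstrap, eff_df$seed,
                       eff_df$n_failed)),
             file.path(out, "effects.txt"))
  message(sprintf("effects: %s",
                  paste(sprintf("day %d OR %.3f", eff_df$day,
                                eff_df$odds_ratio), collapse = "; ")))
  write_meta(out, "run.meta.yaml", config, list(stage = "emulate_estimate"))
  invisible(list(fit = fit, effects = effects))
}
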