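# Delimited-text I/O. All tables are comma-separated UTF-8 with a header row
# and "." as the decimal mark; event histories travel as semicolon-separated
# "day:state" pairs inside one CSV column.

cohort_csv_columns <- c("patient_id", "age", "sex", "charlson_ge2", "crp",
                        "ldh", "log_ddimer", "lymphocytes", "wave",
                        "treatment_day", "history",
                        "flag_hospital_acquired", "flag_readmission",
                        "flag_pre_admission_treatment", "flag_outcome_day0")

#' Write and read patient cohorts as CSV
#'
#' @param cohort a cohort data.frame ([generate_cohort()]).
#' @param path file path.
#' @param admin_censor_day administrative horizon attached to the cohort on
#'   reading (day columns are validated against it).
#' @return `read_cohort()` returns a `ccw_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_csv_columns]
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, admin_censor_day = 45L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, cohort_csv_columns, sprintf("cohort file '%s'", path))
  parsed <- parse_history(df$history)
  for (nm in names(parsed)) df[[nm]] <- parsed[[nm]]
  for (nm in grep("^flag_", names(df), value = TRUE))
    df[[nm]] <- as.logical(df[[nm]])
  df$treatment_day <- suppressWarnings(as.integer(df$treatment_day))
  bad <- c(df$treatment_day, df$event_day, df$icu_day)
  if (any(!is.na(bad) & (bad < 0 | bad > admin_censor_day)))
    stopf("schema error: day values outside [0, %d] in '%s'",
          admin_censor_day, path)
  attr(df, "admin_censor_day") <- as.integer(admin_censor_day)
  class(df) <- c("ccw_cohort", "data.frame")
  df
}

#' Flatten estimator objects for delimited output
#'
#' @param x a `cumhaz_set` or `probtrans_series`-derived occupation list.
#' @param ... unused.
#' @return long-format data.frame.
#' @export
as.data.frame.cumhaz_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$transitions), function(nm) {
    df <- x$transitions[[nm]]
    if (!nrow(df)) return(NULL)
    data.frame(transition = nm, day = df$day, increment = df$increment,
               cumulative = df$cumhaz)
  }))
}

occupation_long <- function(occupation_by_arm) {
  do.call(rbind, lapply(names(occupation_by_arm), function(arm) {
    occ <- occupation_by_arm[[arm]]
    days <- as.integer(sub("day", "", rownames(occ)))
    data.frame(arm = arm,
               day = rep(days, times = ncol(occ)),
               state = rep(colnames(occ), each = nrow(occ)),
               probability = as.vector(occ))
  }))
}
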