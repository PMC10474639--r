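# Independent brute-force oracles used to cross-check the estimators.
# These deliberately use plain loops and explicit formulas, not the package's
# vectorized code paths.

# Written-out Cox partial log-likelihood for a single covariate x,
# with Breslow or Efron handling of tied event times.
oracle_cox_loglik <- function(beta, time, status, x, ties = "breslow") {
  etimes <- sort(unique(time[status == 1]))
  ll <- 0
  for (t in etimes) {
    tied <- which(status == 1 & time == t)
    risk <- which(time >= t)
    d <- length(tied)
    ll <- ll + sum(beta * x[tied])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(beta * x[risk])))
    } else {
      S <- sum(exp(beta * x[risk]))
      D <- sum(exp(beta * x[tied]))
      for (j in seq_len(d)) ll <- ll - log(S - (j - 1) / d * D)
    }
  }
  ll
}

oracle_cox_fit <- function(time, status, x, ties = "breslow") {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, status, x, ties),
                  interval = c(-10, 10), tol = 1e-9)$minimum
}

# Nelson-Aalen increments by direct counting over a clone table with a
# per-clone weight vector (weight applied as the clone's at-risk weight on
# every day, i.e. assumes weights constant over follow-up, as with unit
# weights or a frozen-weight toy set).
oracle_na_increments <- function(clones, w, from, to, horizon = 45) {
  inc <- numeric(horizon)
  for (t in seq_len(horizon)) {
    num <- den <- 0
    for (i in seq_len(nrow(clones))) {
      if (clones$followup_end[i] < t) next
      st <- 1
      if (!is.na(clones$icu_day[i]) && clones$icu_day[i] <= t - 1) st <- 2
      if (st != from) next
      den <- den + w[i]
      moved <- (to == 2 && !is.na(clones$icu_day[i]) && clones$icu_day[i] == t) ||
        (!is.na(clones$event_day[i]) && clones$event_day[i] == t &&
           clones$event_state[i] == to)
      if (moved) num <- num + w[i]
    }
    inc[t] <- if (den > 0) num / den else 0
  }
  inc
}

# Aalen-Johansen by explicit ordered matrix product over the daily grid.
oracle_aj <- function(increments_by_transition, allowed, horizon) {
  P <- diag(5)
  out <- array(0, dim = c(5, 5, horizon + 1))
  out[, , 1] <- P
  for (t in seq_len(horizon)) {
    M <- diag(5)
    for (j in seq_len(nrow(allowed))) {
      l <- allowed[j, 1]; m <- allowed[j, 2]
      dA <- increments_by_transition[[j]][t]
      if (dA > 0) {
        M[l, m] <- M[l, m] + dA
        M[l, l] <- M[l, l] - dA
      }
    }
    P <- P %*% M
    out[, , t + 1] <- P
  }
  out
}

# Closed-form 2x2 odds ratio from a binary outcome table.
oracle_or_2x2 <- function(outcomes) {
  y <- as.integer(outcomes$category) > 1
  tr <- outcomes$arm == "treated"
  (sum(y & tr) * sum(!y & !tr)) / (sum(!y & tr) * sum(y & !tr))
}

# Load the committed hand fixture as a clone table with attributes.
load_toy_clones <- function() {
  path <- system.file("extdata", "toy_clones.csv", package = "ccwmsm")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("censor_day", "icu_day", "event_day", "event_state"))
    df[[nm]] <- suppressWarnings(as.integer(df[[nm]]))
  df$clone_id <- seq_len(nrow(df))
  attr(df, "grace_days") <- 5L
  attr(df, "admin_censor_day") <- 45L
  class(df) <- c("ccw_clones", "data.frame")
  df
}

unit_weight_table <- function(clones) {
  data.frame(clone_id = rep(clones$clone_id, clones$followup_end + 1L),
             patient_id = rep(clones$patient_id, clones$followup_end + 1L),
             arm = rep(clones$arm, clones$followup_end + 1L),
             day = sequence(clones$followup_end + 1L) - 1L,
             weight = 1)
}
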