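# Weighted multi-state estimation on the clone table: a long-format
# counting-process representation, weighted Nelson-Aalen cumulative
# transition hazards, and the Aalen-Johansen product-integral for transition
# probabilities / state-occupation curves.

#' Build the long-format counting-process table
#'
#' One block of rows per clone-day at risk: for each day `t` in
#' `(0, followup_end]` and each allowed destination from the clone's current
#' state, a row with `status = 1` exactly on the observed transition's day
#' and destination. Artificial and administrative censoring produce no
#' `status = 1` row. The weight attached to the risk interval `(t-1, t]` is
#' the clone's weight at `t - 1` (left-continuous carry-forward), so a
#' clone's own censoring day does not inflate its final contribution.
#'
#' @param clones clone table ([clone_and_censor()]).
#' @param weight_table weight table ([compute_weights()]), possibly
#'   truncated.
#' @param structure a [transition_structure()].
#' @param horizon last day of the table (defaults to the administrative
#'   censoring day).
#' @return data.frame of class `ccw_long` with columns `clone_id`, `arm`,
#'   `day`, `from`, `to`, `status`, `weight`.
#' @export
build_long_format <- function(clones, weight_table, structure = transition_structure(),
                              horizon = NULL) {
  if (is.null(horizon)) horizon <- attr(clones, "admin_censor_day") %||% 45L
  n <- nrow(clones)
  fup <- pmin(clones$followup_end, horizon)
  nday <- pmax(fup, 0L)
  clone_row <- rep(seq_len(n), nday)
  day <- sequence(nday)
  icu <- clones$icu_day[clone_row]
  from <- ifelse(!is.na(icu) & icu <= day - 1L, 2L, 1L)
  if (any(!from %in% structure$transient))
    stopf("structural error: clone at risk in non-transient state %d",
          from[!from %in% structure$transient][1])

  # expand each clone-day by the out-degree of its current state
  dests <- lapply(structure$transient, function(s) destinations_from(structure, s))
  names(dests) <- structure$transient
  outdeg <- vapply(dests, length, integer(1))[as.character(from)]
  row_rep <- rep(seq_along(day), outdeg)
  to <- unlist(dests[as.character(from)], use.names = FALSE)

  # observed transitions must lie in the allowed set (checked on the clone
  # table itself so disallowed events cannot be silently dropped)
  allowed_key <- paste(structure$allowed[, 1], structure$allowed[, 2])
  ev_cl <- which(!is.na(clones$event_day) & clones$event_day <= horizon &
                   clones$end_reason == "event")
  if (length(ev_cl)) {
    ev_from <- ifelse(!is.na(clones$icu_day[ev_cl]) &
                        clones$icu_day[ev_cl] <= clones$event_day[ev_cl] - 1L,
                      2L, 1L)
    bad <- setdiff(unique(paste(ev_from, clones$event_state[ev_cl])),
                   allowed_key)
    if (length(bad))
      stopf("structural error: observed transition (%s) not in allowed set",
            gsub(" ", "->", bad[1]))
  }
  if (any(!is.na(clones$icu_day)) && !("1 2" %in% allowed_key))
    stopf("structural error: observed transition (1->2) not in allowed set")

  long <- data.frame(clone_id = clones$clone_id[clone_row][row_rep],
                     arm = clones$arm[clone_row][row_rep],
                     day = day[row_rep],
                     from = from[row_rep],
                     to = to)
  # observed transitions
  ev_day <- clones$event_day[clone_row][row_rep]
  ev_state <- clones$event_state[clone_row][row_rep]
  icu_l <- clones$icu_day[clone_row][row_rep]
  long$status <- as.integer(
    (!is.na(ev_day) & long$day == ev_day & long$to == ev_state) |
      (!is.na(icu_l) & long$day == icu_l & long$to == 2L & long$from == 1L))

  # weight at day - 1, looked up in the weight table
  maxd <- max(weight_table$day, long$day) + 2L
  widx <- match(long$clone_id * maxd + (long$day - 1L),
                weight_table$clone_id * maxd + weight_table$day)
  if (anyNA(widx))
    stopf("weight error: missing weight for clone %s at day %d",
          long$clone_id[which(is.na(widx))[1]],
          long$day[which(is.na(widx))[1]] - 1L)
  long$weight <- weight_table$weight[widx]
  attr(long, "structure") <- structure
  attr(long, "horizon") <- horizon
  class(long) <- c("ccw_long", "data.frame")
  long
}

#' Weighted Nelson-Aalen cumulative transition hazards
#'
#' For each allowed transition `l -> m` and each day `u` with observed
#' transitions, the increment is the weighted number of transitions divided
#' by the weighted number at risk in `l`:
#' `dA_lm(u) = dN^W_lm(u) / Y^W_l(u)`. With all weights equal to 1 this is
#' exactly the standard Nelson-Aalen estimator on the daily grid.
#'
#' @param long_table a [build_long_format()] table.
#' @param structure a [transition_structure()].
#' @return Object of class `cumhaz_set`: per-transition data.frames with
#'   columns `day`, `n_events_w`, `n_risk_w`, `increment`, `cumhaz`.
#' @export
weighted_nelson_aalen <- function(long_table, structure = NULL) {
  if (is.null(structure)) structure <- attr(long_table, "structure")
  if (is.null(structure)) structure <- transition_structure()
  horizon <- attr(long_table, "horizon") %||% max(long_table$day, 0L)
  # one row per clone-day: keep the first destination of each from-state
  first_dest <- vapply(structure$transient,
                       function(s) min(destinations_from(structure, s)),
                       integer(1))
  names(first_dest) <- structure$transient
  risk_rows <- long_table$to == first_dest[as.character(long_table$from)]

  out <- vector("list", nrow(structure$allowed))
  names(out) <- transition_labels(structure)
  for (j in seq_len(nrow(structure$allowed))) {
    l <- structure$allowed[j, "from"]; m <- structure$allowed[j, "to"]
    ev <- long_table$status == 1L & long_table$from == l & long_table$to == m
    if (!any(ev)) {
      out[[j]] <- data.frame(day = integer(0), n_events_w = numeric(0),
                             n_risk_w = numeric(0), increment = numeric(0),
                             cumhaz = numeric(0))
      next
    }
    nw <- rowsum(long_table$weight[ev], long_table$day[ev])
    days <- as.integer(rownames(nw))
    rsel <- risk_rows & long_table$from == l & long_table$day %in% days
    yw_all <- rowsum(long_table$weight[rsel], long_table$day[rsel])
    yw <- yw_all[match(days, as.integer(rownames(yw_all))), 1L]
    if (anyNA(yw) || any(yw <= 0))
      stopf("estimation error: event at a day with zero at-risk weight (%d->%d)",
            l, m)
    inc <- nw[, 1L] / yw
    out[[j]] <- data.frame(day = days, n_events_w = nw[, 1L], n_risk_w = yw,
                           increment = inc, cumhaz = cumsum(inc),
                           row.names = NULL)
  }
  res <- list(transitions = out, structure = structure, horizon = horizon)
  class(res) <- "cumhaz_set"
  res
}

#' @export
print.cumhaz_set <- function(x, ...) {
  cat("Weighted Nelson-Aalen cumulative hazards over",
      length(x$transitions), "transitions (horizon day", x$horizon, ")\n")
  for (nm in names(x$transitions)) {
    df <- x$transitions[[nm]]
    tot <- if (nrow(df)) round(df$cumhaz[nrow(df)], 4) else 0
    cat(sprintf("  %s: %d event day(s), A(horizon) = %s\n", nm, nrow(df), tot))
  }
  invisible(x)
}

#' Weighted Aalen-Johansen transition probabilities
#'
#' Product-integral over the daily grid:
#' `P(s, t) = prod_{u in (s, t]} (I + dA(u))`, where the increment matrix at
#' day `u` has the Nelson-Aalen increments off-diagonal and diagonal entries
#' `1 - sum_m dA_lm(u)`. Rows are stochastic by construction; a negative
#' diagonal (total daily increment above 1) raises an error naming the day.
#'
#' @param cumhaz a [weighted_nelson_aalen()] object.
#' @param structure transition structure (defaults to the one in `cumhaz`).
#' @param s start day of the interval (default 0, hospital admission).
#' @param horizon last day (defaults to the `cumhaz` horizon).
#' @return Object of class `probtrans_series`: `days` (s..horizon) and `P`,
#'   a `5 x 5 x length(days)` array with `P[, , 1]` the identity.
#' @export
aalen_johansen <- function(cumhaz, structure = NULL, s = 0L, horizon = NULL) {
  if (is.null(structure)) structure <- cumhaz$structure
  if (is.null(horizon)) horizon <- cumhaz$horizon
  k <- length(structure$states)
  days <- s:horizon
  P <- array(0, dim = c(k, k, length(days)),
             dimnames = list(names(structure$states),
                             names(structure$states), paste0("day", days)))
  cur <- diag(k)
  P[, , 1L] <- cur
  # increments indexed by day
  inc_by_day <- list()
  for (j in seq_along(cumhaz$transitions)) {
    df <- cumhaz$transitions[[j]]
    l <- cumhaz$structure$allowed[j, "from"]; m <- cumhaz$structure$allowed[j, "to"]
    for (r in seq_len(nrow(df))) {
      d <- as.character(df$day[r])
      inc_by_day[[d]] <- rbind(inc_by_day[[d]], c(l, m, df$increment[r]))
    }
  }
  for (i in seq_along(days)[-1L]) {
    d <- as.character(days[i])
    if (!is.null(inc_by_day[[d]])) {
      M <- diag(k)
      entries <- inc_by_day[[d]]
      for (r in seq_len(nrow(entries))) {
        l <- entries[r, 1L]; m <- entries[r, 2L]
        M[l, m] <- entries[r, 3L]
        M[l, l] <- M[l, l] - entries[r, 3L]
      }
      dg <- diag(M)
      if (any(dg < -1e-9))
        stopf(paste("estimation error: total hazard increment above 1 at day %s;",
                    "grid too coarse or pathological weights"), d)
      # exact-boundary days (everyone at risk moves) can land at -eps
      if (any(dg < 0)) diag(M) <- pmax(dg, 0)
      cur <- cur %*% M
    }
    P[, , i] <- cur
  }
  res <- list(s = s, days = days, P = P, structure = structure)
  class(res) <- "probtrans_series"
  res
}

#' State-occupation probabilities from a transition-probability series
#'
#' @param series a [aalen_johansen()] result.
#' @param from_state starting state (default 1, the normal ward).
#' @return matrix with one row per day and one column per state; each row is
#'   the corresponding row of `P(s, t)` and sums to 1.
#' @export
state_occupation <- function(series, from_state = 1L) {
  occ <- t(series$P[from_state, , ])
  rownames(occ) <- paste0("day", series$days)
  occ
}

#' @export
print.probtrans_series <- function(x, ...) {
  cat("Aalen-Johansen transition probabilities, days", x$s, "..",
      max(x$days), "\n")
  last <- x$P[, , length(x$days)]
  cat("P(s, horizon):\n")
  print(round(last, 4))
  invisible(x)
}
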