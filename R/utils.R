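# Internal helpers shared across modules.

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so library functions never clobber a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Deterministically derive `n` stage seeds (< 2^31) from one root seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("configuration error: '%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("schema error: %s is missing column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

#' Serialize and parse multi-state event histories
#'
#' Histories are stored in delimited text as semicolon-separated `day:state`
#' pairs, e.g. `"0:1;3:2;9:3"` for ward at day 0, ICU entry at day 3 and
#' in-hospital death at day 9. The first pair is always `0:1` (all patients
#' start in the normal ward on the admission day).
#'
#' @param icu_day,event_day,event_state integer vectors (NA where absent):
#'   day of ICU entry, day of the absorbing event, and the absorbing state id.
#' @param history character vector of serialized histories.
#' @return `format_history()` returns a character vector; `parse_history()`
#'   a data.frame with columns `icu_day`, `event_day`, `event_state`.
#' @examples
#' format_history(icu_day = c(3, NA), event_day = c(9, 12),
#'                event_state = c(3, 4))
#' parse_history(c("0:1;3:2;9:3", "0:1;12:4"))
#' @export
format_history <- function(icu_day, event_day, event_state) {
  h <- rep("0:1", length(icu_day))
  has_icu <- !is.na(icu_day)
  h[has_icu] <- paste0(h[has_icu], ";", icu_day[has_icu], ":2")
  has_ev <- !is.na(event_day)
  h[has_ev] <- paste0(h[has_ev], ";", event_day[has_ev], ":",
                      event_state[has_ev])
  h
}

#' @rdname format_history
#' @export
parse_history <- function(history) {
  n <- length(history)
  out <- data.frame(icu_day = rep(NA_integer_, n),
                    event_day = rep(NA_integer_, n),
                    event_state = rep(NA_integer_, n))
  pieces <- strsplit(history, ";", fixed = TRUE)
  for (i in seq_len(n)) {
    p <- pieces[[i]]
    if (length(p) == 0L || p[[1L]] != "0:1")
      stopf("schema error: history '%s' must start with '0:1'", history[i])
    last_day <- 0L
    state <- 1L
    for (entry in p[-1L]) {
      ds <- as.integer(strsplit(entry, ":", fixed = TRUE)[[1L]])
      if (length(ds) != 2L || anyNA(ds))
        stopf("schema error: malformed history entry '%s'", entry)
      if (ds[1L] <= last_day)
        stopf("schema error: history days must be strictly increasing ('%s')",
              history[i])
      if (state %in% c(3L, 4L, 5L))
        stopf("schema error: history continues past absorbing state ('%s')",
              history[i])
      if (ds[2L] == 2L) {
        if (state != 1L)
          stopf("schema error: transition %d->2 not allowed ('%s')",
                state, history[i])
        out$icu_day[i] <- ds[1L]
      } else if (ds[2L] %in% c(3L, 4L, 5L)) {
        out$event_day[i] <- ds[1L]
        out$event_state[i] <- ds[2L]
      } else {
        stopf("schema error: unknown state id %d in history '%s'",
              ds[2L], history[i])
      }
      last_day <- ds[1L]
      state <- ds[2L]
    }
  }
  out
}

# Integer join key for (clone, day) lookups; days are < 64 on the 45-day
# horizon so the key is collision-free and avoids string building.
day_key <- function(id, day) id * 64 + day

# State occupied at the *end* of day t (vectorized over patients/clones).
state_at_day <- function(t, icu_day, event_day, event_state) {
  st <- rep(1L, length(icu_day))
  in_icu <- !is.na(icu_day) & icu_day <= t
  st[in_icu] <- 2L
  absorbed <- !is.na(event_day) & event_day <= t
  st[absorbed] <- event_state[absorbed]
  st
}
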