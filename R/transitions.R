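#' Multi-state transition structure for the hospital model
#'
#' The default model has five states — 1 normal ward, 2 ICU, 3 in-hospital
#' death, 4 discharge home, 5 discharge to another healthcare facility (HCF) —
#' and seven forward-only transitions: the four ward exits
#' 1->2, 1->3, 1->4, 1->5 and the three ICU exits 2->3, 2->4, 2->5. ICU is an
#' intermediate state (no return to the ward); death and the two discharge
#' destinations are absorbing.
#'
#' @param allowed two-column integer matrix of allowed `(from, to)` pairs;
#'   defaults to the seven-transition hospital structure.
#' @return An object of class `transition_structure`: a list with elements
#'   `states` (named integer vector), `allowed` (matrix), `absorbing`
#'   (integer vector) and `transient` (integer vector).
#' @examples
#' ts <- transition_structure()
#' nrow(ts$allowed)  # 7
#' @export
transition_structure <- function(allowed = NULL) {
  states <- c(ward = 1L, icu = 2L, death = 3L, home = 4L, hcf = 5L)
  if (is.null(allowed)) {
    allowed <- cbind(from = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
                     to   = c(2L, 3L, 4L, 5L, 3L, 4L, 5L))
  }
  allowed <- matrix(as.integer(allowed), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  if (any(!allowed %in% states))
    stopf("structural error: transition endpoints must be state ids 1..5")
  absorbing <- setdiff(states, unique(allowed[, "from"]))
  if (any(allowed[, "to"] == allowed[, "from"]))
    stopf("structural error: self-transitions are not allowed")
  if (any(allowed[, "from"] %in% absorbing))
    stopf("structural error: transitions out of an absorbing state")
  structure(list(states = states,
                 allowed = allowed,
                 absorbing = sort(absorbing),
                 transient = sort(unique(allowed[, "from"]))),
            class = "transition_structure")
}

transition_labels <- function(structure) {
  paste0(structure$allowed[, "from"], "->", structure$allowed[, "to"])
}

destinations_from <- function(structure, from) {
  sort(structure$allowed[structure$allowed[, "from"] == from, "to"])
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Multi-state transition structure:", length(x$states), "states,",
      nrow(x$allowed), "transitions\n")
  cat("  transient:", paste(x$transient, collapse = ", "),
      "| absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  cat("  allowed:", paste(transition_labels(x), collapse = ", "), "\n")
  invisible(x)
}
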