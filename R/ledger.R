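#' Exclusion ledgers
#'
#' Cohort construction proceeds by ordered filters; the ledger is the audit
#' trail. Each row records a step name, the number of members removed at
#' that step and the number remaining afterwards, so that
#' `remaining[i] == remaining[i - 1] - removed[i]` for every row after the
#' first.
#'
#' @param start integer, number of members before any filtering.
#' @param label name for the starting row.
#' @return A `data.frame` of class `exclusion_ledger` with columns
#'   `step`, `removed`, `remaining`.
#' @examples
#' led <- exclusion_ledger(100)
#' led <- ledger_add(led, "too_young", 40)
#' ledger_remaining(led)
#' @export
exclusion_ledger <- function(start, label = "initial") {
  start <- as.integer(start)
  if (is.na(start) || start < 0) stop("`start` must be a nonnegative count")
  structure(
    data.frame(step = label, removed = 0L, remaining = start,
               stringsAsFactors = FALSE),
    class = c("exclusion_ledger", "data.frame")
  )
}

#' Append a filtering step to a ledger
#'
#' @param ledger an `exclusion_ledger`.
#' @param step name of the filtering step.
#' @param removed count removed at this step.
#' @return The extended ledger.
#' @export
ledger_add <- function(ledger, step, removed) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  removed <- as.integer(removed)
  prev <- ledger$remaining[nrow(ledger)]
  if (is.na(removed) || removed < 0) stop("`removed` must be a nonnegative count")
  if (removed > prev) {
    stop(sprintf("step '%s' removes %d but only %d remain", step, removed, prev))
  }
  out <- rbind(ledger, data.frame(step = step, removed = removed,
                                  remaining = prev - removed,
                                  stringsAsFactors = FALSE))
  class(out) <- c("exclusion_ledger", "data.frame")
  out
}

#' Replay a cascade of removal counts
#'
#' Builds a full ledger from a starting count and a named vector of removal
#' counts applied in order. Useful for auditing a published exclusion
#' cascade: the final `remaining` must reproduce the published cohort size.
#'
#' @param start starting count.
#' @param removed named integer vector of per-step removal counts, applied
#'   in order.
#' @return An `exclusion_ledger`.
#' @export
ledger_replay <- function(start, removed) {
  if (is.null(names(removed)) || any(!nzchar(names(removed)))) {
    stop("`removed` must be a fully named vector")
  }
  led <- exclusion_ledger(start)
  for (i in seq_along(removed)) {
    led <- ledger_add(led, names(removed)[i], removed[[i]])
  }
  led
}

#' Final remaining count of a ledger
#' @param ledger an `exclusion_ledger`.
#' @return integer count remaining after the last step.
#' @export
ledger_remaining <- function(ledger) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  ledger$remaining[nrow(ledger)]
}

#' Validate ledger arithmetic
#'
#' @param ledger an `exclusion_ledger`.
#' @return `TRUE` invisibly; errors if the running arithmetic is broken.
#' @export
ledger_validate <- function(ledger) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  if (any(ledger$removed < 0) || any(ledger$remaining < 0)) {
    stop("ledger counts must be nonnegative")
  }
  if (nrow(ledger) > 1L) {
    expect <- ledger$remaining[-nrow(ledger)] - ledger$removed[-1L]
    if (!all(expect == ledger$remaining[-1L])) {
      stop("ledger arithmetic broken: remaining[i] != remaining[i-1] - removed[i]")
    }
  }
  invisible(TRUE)
}

# concatenate two ledgers, re-checking the join
ledger_bind <- function(a, b) {
  stopifnot(inherits(a, "exclusion_ledger"), inherits(b, "exclusion_ledger"))
  out <- rbind(a, b[-1L, , drop = FALSE])
  class(out) <- c("exclusion_ledger", "data.frame")
  out
}
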