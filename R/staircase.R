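# Two-consecutive adaptive staircase: difficulty moves one level harder
# after two consecutive correct trials, one level easier after two
# consecutive errors, and stays put otherwise. With a psychometric function
# that decreases across levels and crosses 50%, the chain's marginal
# accuracy converges to approximately 50%.

#' Create a staircase state
#'
#' @param level Current difficulty level, 1 (easiest) to 10 (hardest).
#' @param streak_outcome `"correct"`, `"error"` or `"none"`.
#' @param streak_len Current streak length, 0..2; 0 iff outcome is "none".
#' @return A list of class `staircase_state`.
#' @export
staircase_state <- function(level = 5L, streak_outcome = "none", streak_len = 0L) {
  stopifnot(level %in% 1:10, streak_outcome %in% c("correct", "error", "none"),
            streak_len %in% 0:2,
            (streak_len == 0L) == (streak_outcome == "none"))
  structure(list(level = as.integer(level), streak_outcome = streak_outcome,
                 streak_len = as.integer(streak_len)),
            class = "staircase_state")
}

#' Advance the staircase by one trial outcome
#'
#' Upgrading means one level harder (clamped at 10); downgrading one level
#' easier (clamped at 1). The streak resets after every level change.
#'
#' @param state A [staircase_state()].
#' @param correct Logical, whether the initial decision was correct.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  outcome <- if (correct) "correct" else "error"
  if (state$streak_outcome == outcome && state$streak_len == 1L) {
    lev <- if (correct) min(state$level + 1L, 10L) else max(state$level - 1L, 1L)
    staircase_state(lev, "none", 0L)
  } else {
    staircase_state(state$level, outcome, 1L)
  }
}
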