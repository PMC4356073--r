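#' Saccade decision rule
#'
#' The decision takes the motor (MOT) group with the greatest spike count in
#' the 500 ms window before the response occurs; if the overall firing rate of
#' the motor layer (all four groups pooled) does not exceed the threshold, a
#' uniformly random direction is chosen instead.
#'
#' @param window_ms Decision window length (ms), default 500.
#' @param threshold_hz Layer-wide rate threshold (Hz), default 6.
#' @return List with class `"decision_rule"`.
#' @export
decision_rule <- function(window_ms = 500, threshold_hz = 6) {
  stopifnot(window_ms > 0, threshold_hz >= 0)
  structure(list(window_ms = window_ms, threshold_hz = threshold_hz),
            class = "decision_rule")
}

#' Decide a saccade direction from motor spike counts
#'
#' @param counts Integer vector of length 4: spike counts of the four MOT
#'   groups in the decision window.
#' @param overall_rate Mean firing rate (Hz) across all MOT neurons in the
#'   window.
#' @param rule A [decision_rule()].
#' @return List with `choice` (direction `0:3`) and `basis` (`"winner"` or
#'   `"random"`). Ties among maxima are broken uniformly at random; the
#'   random fallback draws uniformly from all four directions. Uses R's RNG.
#' @examples
#' set.seed(1)
#' decide(c(120, 10, 8, 9), overall_rate = 12)
#' @export
decide <- function(counts, overall_rate, rule = decision_rule()) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  counts <- unname(counts)
  if (overall_rate > rule$threshold_hz) {
    best <- which(counts == max(counts))
    choice <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
    list(choice = choice - 1L, basis = "winner")
  } else {
    list(choice = sample.int(4, 1) - 1L, basis = "random")
  }
}

#' Score a session of behaviour records
#'
#' @param records data.frame with columns `trial`, `target`, `choice`,
#'   `basis`; the `correct` and `perseverative` columns are (re)computed here.
#'   A response is perseverative iff the chosen direction equals the previous
#'   trial's choice (the first trial is never perseverative); random-fallback
#'   choices are scored exactly like winner choices. Set
#'   `perseverative_requires_error = TRUE` to count only repeats that are also
#'   errors.
#' @param perseverative_requires_error Logical, default `FALSE` (a repeat is
#'   perseverative whether or not it is correct).
#' @return List of class `"session_score"`: `records` (with `correct` and
#'   `perseverative` flags), `percent_correct`, `percent_perseverative`,
#'   `percent_random`, `n_trials`.
#' @export
score_session <- function(records, perseverative_requires_error = FALSE) {
  stopifnot(nrow(records) >= 1,
            all(c("target", "choice", "basis") %in% names(records)))
  n <- nrow(records)
  records <- records[order(if ("trial" %in% names(records)) records$trial
                           else seq_len(n)), ]
  records$correct <- records$choice == records$target
  prev <- c(NA, records$choice[-n])
  records$perseverative <- !is.na(prev) & records$choice == prev
  if (perseverative_requires_error) {
    records$perseverative <- records$perseverative & !records$correct
  }
  structure(list(
    records = records,
    n_trials = n,
    percent_correct = 100 * sum(records$correct) / n,
    percent_perseverative = 100 * sum(records$perseverative) / n,
    percent_random = 100 * sum(records$basis == "random") / n),
    class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf("<session_score> %d trials: %.1f%% correct, %.1f%% perseverative, %.1f%% random\n",
              x$n_trials, x$percent_correct, x$percent_perseverative,
              x$percent_random))
  invisible(x)
}
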