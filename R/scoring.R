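#' Scoring configuration for bimanual press classification
#'
#' A press is classified by comparing its time to the nearest
#' opposite-hand presses of the same and of the different finger,
#' within `match_window_s` seconds. Exact ties and presses with no
#' opposite-hand press in the window are resolved by policy.
#'
#' @param match_window_s maximum |time difference| (s) for an
#'   opposite-hand press to count as a pairing candidate; a sensible
#'   default is half the pacing period.
#' @param tie_policy what an exact tie (same distance to both fingers)
#'   counts as: `"incorrect"` (default, conservative) or `"exclude"`.
#' @param unmatched_policy what a press with no opposite-hand press in
#'   the window counts as: `"incorrect"` (default; a press without a
#'   counterpart is not a correct bimanual movement) or `"exclude"`.
#' @return An object of class `score_config`.
#' @export
score_config <- function(match_window_s = 1 / 3,
                         tie_policy = c("incorrect", "exclude"),
                         unmatched_policy = c("incorrect", "exclude")) {
  if (!is.numeric(match_window_s) || match_window_s <= 0)
    stop_validation("match_window_s must be > 0")
  structure(list(match_window_s = match_window_s,
                 tie_policy = match.arg(tie_policy),
                 unmatched_policy = match.arg(unmatched_policy)),
            class = "score_config")
}

#' Classify one press as correct / incorrect / excluded
#'
#' The correctness rule: let `d_same` be the smallest |time difference|
#' from this press to an opposite-hand press of the SAME finger within
#' the window, and `d_diff` likewise for the DIFFERENT finger. An
#' in-phase press is correct iff `d_same < d_diff` (mirror-symmetric
#' pressing); an anti-phase press is correct iff `d_diff < d_same`
#' (parallel pressing). Ties and unmatched presses follow the config
#' policies.
#'
#' @param event one-row data.frame (or list) with at least `hand`,
#'   `finger`, `time_s`.
#' @param other_hand_events data.frame of presses of the opposite hand
#'   in the same run.
#' @param mode `"in_phase"` or `"anti_phase"`.
#' @param config a [score_config()].
#' @return one of `"correct"`, `"incorrect"`, `"excluded"`.
#' @export
classify_press <- function(event, other_hand_events,
                           mode = c("in_phase", "anti_phase"),
                           config = score_config()) {
  mode <- match.arg(mode)
  if (nrow(other_hand_events) &&
      any(other_hand_events$hand == event$hand))
    stop_validation("other_hand_events must all be from the opposite hand")
  dt <- abs(other_hand_events$time_s - event$time_s)
  inside <- dt <= config$match_window_s
  d_same <- suppressWarnings(
    min(dt[inside & other_hand_events$finger == event$finger]))
  d_diff <- suppressWarnings(
    min(dt[inside & other_hand_events$finger != event$finger]))
  verdict(d_same, d_diff, mode, config)
}

verdict <- function(d_same, d_diff, mode, config) {
  if (is.infinite(d_same) && is.infinite(d_diff))
    return(if (config$unmatched_policy == "exclude") "excluded"
           else "incorrect")
  if (d_same == d_diff)
    return(if (config$tie_policy == "exclude") "excluded" else "incorrect")
  ok <- if (mode == "in_phase") d_same < d_diff else d_diff < d_same
  if (ok) "correct" else "incorrect"
}

# Vectorized classification of every press of one mode within a
# subject x run event table.
classify_all <- function(events, mode, config) {
  ev <- events[events$mode == mode, , drop = FALSE]
  n <- nrow(ev)
  if (!n) return(character(0))
  res <- character(n)
  for (h in HANDS) {
    idx <- which(ev$hand == h)
    if (!length(idx)) next
    opp <- events[events$hand != h, , drop = FALSE]  # any mode: candidates
    for (i in idx) {
      dt <- abs(opp$time_s - ev$time_s[i])
      inside <- dt <= config$match_window_s
      d_same <- suppressWarnings(min(dt[inside & opp$finger == ev$finger[i]]))
      d_diff <- suppressWarnings(min(dt[inside & opp$finger != ev$finger[i]]))
      res[i] <- verdict(d_same, d_diff, mode, config)
    }
  }
  res
}

#' Accuracy rate for one subject x run x mode
#'
#' The accuracy rate is the number of correct presses divided by the
#' total number of (non-excluded) presses of that mode. Spurious extra
#' presses are part of the denominator unless the policies exclude
#' them.
#'
#' @param events press-event data.frame for one subject x run (both
#'   hands; may contain both modes, only `mode` rows are scored, with
#'   the opposite hand's full stream as pairing candidates).
#' @param mode `"in_phase"` or `"anti_phase"`.
#' @param config a [score_config()].
#' @param pacing_hz optional pacing frequency stored on the record.
#' @return one-row data.frame: `subject_id`, `mode`, `pacing_hz`,
#'   `n_correct`, `n_presses`, `accuracy` (0 with a warning when no
#'   presses).
#' @export
accuracy_rate <- function(events, mode = c("in_phase", "anti_phase"),
                          config = score_config(), pacing_hz = NA_real_) {
  mode <- match.arg(mode)
  subject <- if (nrow(events)) events$subject_id[1] else NA_character_
  if (nrow(events) && length(unique(events$subject_id)) > 1)
    stop_validation("accuracy_rate scores one subject at a time")
  cls <- classify_all(events, mode, config)
  n_press <- sum(cls != "excluded")
  n_corr <- sum(cls == "correct")
  if (n_press == 0) {
    warning("no scorable presses for mode ", mode, call. = FALSE)
    acc <- 0
  } else acc <- n_corr / n_press
  data.frame(subject_id = subject, mode = mode, pacing_hz = pacing_hz,
             n_correct = n_corr, n_presses = n_press, accuracy = acc)
}

#' Select the pacing frequency maximizing the group performance gap
#'
#' Among the tested pacing frequencies, returns the one maximizing the
#' young-minus-elderly difference in mean anti-phase accuracy, subject
#' to the young group's mean anti-phase accuracy staying at or above
#' `young_floor` (the task must remain manageable for the young group).
#' Ties break toward the lower frequency.
#'
#' @param records data.frame of accuracy records with columns `group`
#'   (`"young"`/`"elderly"`), `mode`, `pacing_hz`, `accuracy` (one row
#'   per subject x condition, or already-aggregated means).
#' @param young_floor minimum acceptable young anti-phase mean accuracy
#'   (default 0.8; set 0 to disable).
#' @return the selected pacing frequency (scalar).
#' @export
select_frequency <- function(records, young_floor = 0.8) {
  need <- c("group", "mode", "pacing_hz", "accuracy")
  if (!all(need %in% names(records)))
    stop_validation("records need columns ", paste(need, collapse = ", "))
  anti <- records[records$mode == "anti_phase", , drop = FALSE]
  freqs <- sort(unique(records$pacing_hz))
  if (length(freqs) < 2)
    stop_validation("need at least two pacing frequencies")
  cells <- expand.grid(group = c("young", "elderly"), pacing_hz = freqs,
                       stringsAsFactors = FALSE)
  means <- mapply(function(g, f)
    mean(anti$accuracy[anti$group == g & anti$pacing_hz == f]),
    cells$group, cells$pacing_hz)
  if (anyNA(means))
    stop_validation("missing anti-phase cells: ",
                    paste(sprintf("%s@%g", cells$group[is.na(means)],
                                  cells$pacing_hz[is.na(means)]),
                          collapse = ", "))
  young <- means[cells$group == "young"]
  elderly <- means[cells$group == "elderly"]
  gap <- young - elderly
  feasible <- young >= young_floor
  if (!any(feasible))
    feasible <- rep(TRUE, length(freqs))  # floor unattainable: best gap
  cand <- which(feasible)
  best <- cand[order(-gap[cand], freqs[cand])][1]
  freqs[best]
}

#' Write accuracy records as CSV
#' @param records accuracy record data.frame.
#' @param path file path.
#' @export
write_accuracy_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
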