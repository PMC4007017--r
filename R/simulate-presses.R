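#' Error structure of a simulated participant
#'
#' Four knobs control how a synthetic participant deviates from perfect
#' cued bimanual pressing:
#' * `timing_sd_s` — Gaussian jitter (s) added independently to every press;
#' * `swap_prob`   — probability that a whole cycle slips into the mirror
#'   pattern (one hand presses the wrong finger), the signature of a
#'   phase transition from anti-phase towards in-phase coordination;
#' * `miss_prob`   — probability that a cued press is omitted;
#' * `extra_prob`  — probability of one spurious press per cycle, at a
#'   uniform time within the cycle, random hand and finger.
#'
#' @param timing_sd_s,swap_prob,miss_prob,extra_prob see above.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(timing_sd_s = 0.05, swap_prob = 0,
                             miss_prob = 0, extra_prob = 0) {
  if (!is.numeric(timing_sd_s) || timing_sd_s < 0)
    stop_validation("timing_sd_s must be >= 0")
  for (p in c(swap_prob, miss_prob, extra_prob))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop_validation("swap_prob, miss_prob and extra_prob must lie in [0, 1]")
  structure(list(timing_sd_s = timing_sd_s, swap_prob = swap_prob,
                 miss_prob = miss_prob, extra_prob = extra_prob),
            class = "behavior_profile")
}

#' Simulate a stream of button presses for one run
#'
#' Each pacing cycle cues one press per hand (the finger pair depends on
#' the block's coupling mode and the cycle parity). With probability
#' `swap_prob` the cycle slips into the mirror pattern: the left hand
#' presses the other finger, which converts an anti-phase cycle into an
#' in-phase one and vice versa. Presses are jittered, omitted, and
#' augmented with spurious presses according to the profile.
#'
#' @param schedule a [task_schedule()].
#' @param profile a [behavior_profile()].
#' @param subject_id identifier stored on each event.
#' @param seed integer seed; fixed seed gives identical output.
#' @return data.frame of press events with columns `subject_id`,
#'   `run_id`, `block_index`, `mode`, `hand`, `finger`, `time_s`,
#'   ordered by time.
#' @export
simulate_presses <- function(schedule, profile, subject_id = "sim",
                             seed = NULL) {
  stopifnot(inherits(schedule, "task_schedule"),
            inherits(profile, "behavior_profile"))
  cues <- cue_onsets(schedule)
  with_seed(seed, {
    n <- nrow(cues)
    if (n == 0L) return(empty_press_table())
    swap <- stats::runif(n) < profile$swap_prob
    period <- 1 / schedule$pacing_hz
    even <- cues$cycle %% 2 == 0
    anti <- cues$mode == "anti_phase"
    # right hand follows the cue; in-phase mirrors it, anti-phase opposes
    fing_R <- ifelse(even, "index", "middle")
    fing_L <- ifelse(anti, ifelse(even, "middle", "index"), fing_R)
    # mirror slip: left hand hits the other finger
    fing_L[swap] <- ifelse(fing_L[swap] == "index", "middle", "index")
    ev <- data.frame(
      block_index = rep(cues$block_index, 2L),
      mode = rep(cues$mode, 2L),
      hand = rep(HANDS, each = n),
      finger = c(fing_L, fing_R),
      time_s = rep(cues$time_s, 2L) +
        stats::rnorm(2L * n, 0, profile$timing_sd_s))
    ev <- ev[stats::runif(2L * n) >= profile$miss_prob, , drop = FALSE]
    fires <- which(stats::runif(n) < profile$extra_prob)
    if (length(fires)) {
      ev <- rbind(ev, data.frame(
        block_index = cues$block_index[fires],
        mode = cues$mode[fires],
        hand = sample(HANDS, length(fires), replace = TRUE),
        finger = sample(FINGERS, length(fires), replace = TRUE),
        time_s = cues$time_s[fires] +
          stats::runif(length(fires), 0, period)))
    }
    if (!nrow(ev)) return(empty_press_table())
    ev$subject_id <- subject_id
    ev$run_id <- schedule$run_id
    ev <- ev[order(ev$time_s),
             c("subject_id", "run_id", "block_index", "mode",
               "hand", "finger", "time_s")]
    rownames(ev) <- NULL
    ev
  })
}

empty_press_table <- function() {
  data.frame(subject_id = character(), run_id = character(),
             block_index = integer(), mode = character(),
             hand = character(), finger = character(), time_s = numeric())
}

#' Read/write press-event tables as TSV
#'
#' The on-disk dialect has columns `subject_id`, `run_id`, `block_index`,
#' `mode`, `hand` (L/R), `finger` (index/middle), `time_s` (seconds from
#' run start, written with 3 decimals).
#'
#' @param events a press-event data.frame as from [simulate_presses()].
#' @param path file path.
#' @export
write_press_tsv <- function(events, path) {
  ev <- events
  ev$time_s <- sprintf("%.3f", ev$time_s)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_press_tsv
#' @export
read_press_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(subject_id = "character",
                                         run_id = "character"))
  bad_hand <- setdiff(unique(ev$hand), HANDS)
  bad_fing <- setdiff(unique(ev$finger), FINGERS)
  if (length(bad_hand) || length(bad_fing) || any(ev$time_s < 0))
    stop_validation("malformed press table: hand/finger outside enums ",
                    "or negative time")
  ev
}
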