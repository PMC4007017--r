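#' Block/cue timing structure of one task run
#'
#' A run alternates rest and task blocks, starting and ending with rest
#' (the default is 9 rest + 8 task blocks of 20 s each, a 340 s run).
#' Task blocks alternate between the two coupling modes; within a task
#' block a visual pacing cue alternates at `pacing_hz` cycles per second.
#' BOLD volumes are acquired every `tr_s` seconds; with the defaults the
#' final partial volume is not acquired, so `n_volumes = 113` covers
#' 339 s of the 340 s run.
#'
#' @param pacing_hz pacing-cue frequency in cycles/second (one of 1.0,
#'   1.5, 2.0 in the canonical design, but any positive value is allowed).
#' @param run_id identifier for the run; defaults to `"run_<pacing_hz>"`.
#' @param rest_block_s rest (and task) block duration in seconds.
#' @param n_rest_blocks,n_task_blocks block counts; rest and task blocks
#'   strictly alternate, so `n_rest_blocks == n_task_blocks + 1`.
#' @param mode_sequence coupling mode of each task block, values in
#'   `c("in_phase", "anti_phase")`; default alternates, four of each.
#' @param tr_s repetition time (volume spacing) in seconds.
#' @param n_volumes number of volumes acquired; must fit in the run
#'   (`n_volumes * tr_s <= duration + tr_s`).
#' @return An object of class `task_schedule`.
#' @examples
#' sch <- task_schedule(1.5)
#' schedule_duration(sch) # 340
#' @export
task_schedule <- function(pacing_hz = 1.5,
                          run_id = NULL,
                          rest_block_s = 20,
                          n_rest_blocks = 9,
                          n_task_blocks = 8,
                          mode_sequence = NULL,
                          tr_s = 3,
                          n_volumes = 113) {
  if (!is.numeric(pacing_hz) || length(pacing_hz) != 1L || pacing_hz <= 0)
    stop_validation("pacing_hz must be a single positive number")
  if (rest_block_s <= 0 || tr_s <= 0)
    stop_validation("block duration and TR must be positive")
  if (n_rest_blocks < 1 || n_task_blocks < 0 ||
      n_rest_blocks != n_task_blocks + 1L)
    stop_validation("blocks must strictly alternate rest/task ",
                    "(n_rest_blocks == n_task_blocks + 1, n_rest_blocks >= 1)")
  if (is.null(mode_sequence)) {
    mode_sequence <- rep(MODES, length.out = n_task_blocks)
  }
  if (length(mode_sequence) != n_task_blocks ||
      !all(mode_sequence %in% MODES))
    stop_validation("mode_sequence must assign one of ",
                    paste(MODES, collapse = "/"), " to each task block")
  duration <- rest_block_s * (n_rest_blocks + n_task_blocks)
  if (n_volumes < 1 || n_volumes * tr_s > duration + tr_s)
    stop_validation("n_volumes * tr_s must not exceed run duration + one TR")
  structure(list(
    run_id = run_id %||% sprintf("run_%g", pacing_hz),
    rest_block_s = rest_block_s,
    n_rest_blocks = n_rest_blocks,
    n_task_blocks = n_task_blocks,
    mode_sequence = mode_sequence,
    pacing_hz = pacing_hz,
    tr_s = tr_s,
    n_volumes = as.integer(n_volumes)
  ), class = "task_schedule")
}

#' @rdname task_schedule
#' @param overrides named list of `task_schedule()` arguments to override.
#' @export
generate_schedule <- function(pacing_hz = 1.5, overrides = list()) {
  do.call(task_schedule, c(list(pacing_hz = pacing_hz), overrides))
}

#' Total run duration in seconds
#' @param schedule a [task_schedule()].
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  schedule$rest_block_s * (schedule$n_rest_blocks + schedule$n_task_blocks)
}

#' Task-block onset/offset table for a schedule
#'
#' @param schedule a [task_schedule()].
#' @return data.frame with columns `block_index` (1-based over task
#'   blocks), `mode`, `onset_s`, `offset_s`.
#' @export
task_blocks <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  n <- schedule$n_task_blocks
  if (n == 0L)
    return(data.frame(block_index = integer(), mode = character(),
                      onset_s = numeric(), offset_s = numeric()))
  # rest, task, rest, task, ... , rest: task block k starts after k rests
  # and k-1 task blocks
  onset <- schedule$rest_block_s * (2 * seq_len(n) - 1)
  data.frame(block_index = seq_len(n),
             mode = schedule$mode_sequence,
             onset_s = onset,
             offset_s = onset + schedule$rest_block_s)
}

#' Cue-onset times for one or all task blocks
#'
#' A pacing cycle is one alternation of the cue-picture pair; cue onsets
#' fall at `k / pacing_hz` seconds after block onset, for every `k >= 0`
#' with onset strictly before block offset.
#'
#' @param schedule a [task_schedule()].
#' @param block_index task-block index, or `NULL` for all task blocks.
#' @return data.frame with columns `block_index`, `mode`, `cycle`
#'   (0-based alternation index within the block), `time_s`.
#' @export
cue_onsets <- function(schedule, block_index = NULL) {
  blocks <- task_blocks(schedule)
  if (!is.null(block_index)) blocks <- blocks[blocks$block_index %in% block_index, ]
  if (nrow(blocks) == 0L)
    return(data.frame(block_index = integer(), mode = character(),
                      cycle = integer(), time_s = numeric()))
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    k <- seq(0L, ceiling((b$offset_s - b$onset_s) * schedule$pacing_hz))
    t <- b$onset_s + k / schedule$pacing_hz
    keep <- t < b$offset_s - 1e-9
    data.frame(block_index = b$block_index, mode = b$mode,
               cycle = k[keep], time_s = t[keep])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("task_schedule '%s': %d rest + %d task blocks x %gs = %gs, %g Hz pacing, TR %gs, %d volumes\n",
              x$run_id, x$n_rest_blocks, x$n_task_blocks, x$rest_block_s,
              schedule_duration(x), x$pacing_hz, x$tr_s, x$n_volumes))
  invisible(x)
}
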