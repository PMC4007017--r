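mk_event <- function(hand, finger, t)
  data.frame(subject_id = "s1", run_id = "r1", block_index = 1L,
             mode = "in_phase", hand = hand, finger = finger, time_s = t)

test_that("the correctness rule follows the same/different-finger latency table", {
  ri <- mk_event("R", "index", 10.00)
  left <- rbind(mk_event("L", "index", 10.02),   # LI
                mk_event("L", "middle", 10.30))  # LM
  cfg <- score_config(match_window_s = 1 / 3)
  # in-phase: same finger closer (LI < LM) -> correct
  expect_equal(classify_press(ri, left, "in_phase", cfg), "correct")
  # anti-phase requires LM < LI -> incorrect with the same timings
  expect_equal(classify_press(ri, left, "anti_phase", cfg), "incorrect")
})

test_that("ties and unmatched presses follow the configured policies", {
  ri <- mk_event("R", "index", 10.00)
  # 0.25 is exactly representable, so both distances tie exactly
  tie <- rbind(mk_event("L", "index", 10.25), mk_event("L", "middle", 9.75))
  expect_equal(classify_press(ri, tie, "in_phase",
                              score_config(1 / 3, tie_policy = "incorrect")),
               "incorrect")
  expect_equal(classify_press(ri, tie, "in_phase",
                              score_config(1 / 3, tie_policy = "exclude")),
               "excluded")
  far <- mk_event("L", "index", 11.00)  # outside the window
  expect_equal(classify_press(ri, far, "in_phase",
                              score_config(1 / 3,
                                           unmatched_policy = "exclude")),
               "excluded")
  expect_equal(classify_press(ri, far, "in_phase",
                              score_config(1 / 3,
                                           unmatched_policy = "incorrect")),
               "incorrect")
  # same-hand candidates are a usage error
  expect_error(classify_press(ri, mk_event("R", "middle", 10.0),
                              "in_phase", score_config(1 / 3)),
               class = "bimansem_validation_error")
})

test_that("accuracy_rate counts correct over non-excluded presses", {
  sch <- task_schedule(1.5)
  ev <- simulate_presses(sch, behavior_profile(timing_sd_s = 0), seed = 1)
  # corrupt 2 of 8 scored in-phase presses in one block: flip left finger
  idx <- which(ev$mode == "in_phase" & ev$hand == "L")[1:30]
  ev$finger[idx] <- ifelse(ev$finger[idx] == "index", "middle", "index")
  rec <- accuracy_rate(ev, "in_phase", score_config(1 / 3))
  # each flipped left press and its right partner both become incorrect
  expect_equal(rec$n_presses, 240L)
  expect_equal(rec$n_correct, 240L - 60L)
  expect_equal(rec$accuracy, 0.75)
  # empty input: zero accuracy, flagged
  expect_warning(r0 <- accuracy_rate(ev[0, ], "in_phase"))
  expect_equal(r0$n_presses, 0L)
  expect_equal(r0$accuracy, 0)
})

test_that("accuracy is invariant under a global time shift", {
  sch <- task_schedule(1.5)
  ev <- simulate_presses(sch, behavior_profile(timing_sd_s = 0.03,
                                               swap_prob = 0.2), seed = 7)
  shifted <- ev
  shifted$time_s <- shifted$time_s + 123.456
  for (m in c("in_phase", "anti_phase"))
    expect_equal(accuracy_rate(shifted, m, score_config(1 / 3))$accuracy,
                 accuracy_rate(ev, m, score_config(1 / 3))$accuracy)
})

test_that("within-hand finger swap exchanges the modes exactly (duality)", {
  sch <- task_schedule(1.5)
  ev <- simulate_presses(sch, behavior_profile(timing_sd_s = 0.04,
                                               swap_prob = 0.3,
                                               miss_prob = 0.05), seed = 11)
  # relabel the left hand's fingers; the same presses must then classify
  # under the opposite mode's rule exactly as the originals did under
  # their own rule
  swapped <- ev
  li <- swapped$hand == "L"
  swapped$finger[li] <- ifelse(swapped$finger[li] == "index",
                               "middle", "index")
  swapped$mode <- ifelse(swapped$mode == "in_phase",
                         "anti_phase", "in_phase")
  cfg <- score_config(1 / 3)
  for (m in c("in_phase", "anti_phase")) {
    dual <- setdiff(c("in_phase", "anti_phase"), m)
    a <- accuracy_rate(ev, m, cfg)
    s <- accuracy_rate(swapped, dual, cfg)
    expect_equal(s$n_correct, a$n_correct)
    expect_equal(s$n_presses, a$n_presses)
  }
})

test_that("accuracy is monotone non-increasing in swap_prob on average", {
  sch <- task_schedule(1.5)
  mean_acc <- function(q) {
    mean(sapply(1:5, function(s)
      accuracy_rate(simulate_presses(sch, behavior_profile(swap_prob = q),
                                     seed = 100 + s),
                    "anti_phase", score_config(1 / 3))$accuracy))
  }
  accs <- vapply(c(0, 0.25, 0.5, 0.75, 1), mean_acc, numeric(1))
  expect_true(all(diff(accs) <= 0.02))
  expect_true(all(accs >= 0 & accs <= 1))
})

test_that("select_frequency maximizes the anti-phase gap under the young floor", {
  recs <- expand.grid(group = c("young", "elderly"),
                      mode = c("in_phase", "anti_phase"),
                      pacing_hz = c(1.0, 1.5, 2.0),
                      stringsAsFactors = FALSE)
  recs$accuracy <- 0.9
  y <- recs$group == "young" & recs$mode == "anti_phase"
  e <- recs$group == "elderly" & recs$mode == "anti_phase"
  recs$accuracy[y] <- c(0.96, 0.92, 0.66)[match(recs$pacing_hz[y],
                                                c(1, 1.5, 2))]
  recs$accuracy[e] <- c(0.45, 0.39, 0.35)[match(recs$pacing_hz[e],
                                                c(1, 1.5, 2))]
  # 2.0 Hz has gap 0.31 but fails the 0.8 young floor; 1.5 beats 1.0
  expect_equal(select_frequency(recs), 1.5)
  # identical group means -> lowest frequency wins the tie
  recs$accuracy <- 0.9
  expect_equal(select_frequency(recs), 1.0)
  # missing cells are refused
  expect_error(select_frequency(recs[recs$group == "young", ]),
               class = "bimansem_validation_error")
})

test_that("with no floor, selection equals the brute-force argmax of the gap", {
  set.seed(202)
  for (rep in 1:20) {
    freqs <- c(1.0, 1.5, 2.0)
    recs <- expand.grid(group = c("young", "elderly"),
                        mode = c("in_phase", "anti_phase"),
                        pacing_hz = freqs, stringsAsFactors = FALSE)
    recs$accuracy <- runif(nrow(recs))
    got <- select_frequency(recs, young_floor = 0)
    anti <- recs[recs$mode == "anti_phase", ]
    gap <- vapply(freqs, function(f)
      mean(anti$accuracy[anti$group == "young" & anti$pacing_hz == f]) -
        mean(anti$accuracy[anti$group == "elderly" & anti$pacing_hz == f]),
      numeric(1))
    expect_equal(got, freqs[which.max(gap)])
  }
})
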