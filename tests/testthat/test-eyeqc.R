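test_that("amplitude classification follows the stated ranges and gap", {
  r <- saccade_rules()
  expect_equal(classify_amplitude(c(4, 6, 2.5), r), c("small", "small", "small"))
  expect_equal(classify_amplitude(c(7, 14.9), r), c("medium", "medium"))
  expect_equal(classify_amplitude(c(30, 20.01), r), c("large", "large"))
  expect_equal(classify_amplitude(c(15, 17, 20), r), rep("unclassified", 3))
  expect_error(classify_amplitude(2, r), "threshold")
  expect_error(saccade_rules(detect_threshold_deg = 3), "threshold")
})

test_that("detector finds steps, ignores sub-threshold oscillation, flags missing", {
  mk_trace <- function(x) structure(
    list(time_s = (seq_along(x) - 1) / 60, gaze_x_deg = x, sampling_hz = 60,
         run_id = 1, subject_id = "s", truth = NULL), class = "eye_trace")
  # single 4-degree step
  ev <- detect_saccades(mk_trace(c(rep(0, 60), rep(4, 60))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_deg, 4, tolerance = 0.05)
  expect_equal(ev$class, "small")
  expect_equal(ev$direction, "right")
  # ±1.5 degree oscillation never deviates 2 degrees from tracked fixation
  osc <- 1.5 * sin(2 * pi * (0:359) / 30)
  expect_equal(nrow(detect_saccades(mk_trace(osc))), 0)
  # all-missing trace: empty with flag
  ev <- detect_saccades(mk_trace(rep(NA_real_, 120)))
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "missing_data"))
})

test_that("clean simulated blocks validate with exactly six saccades", {
  p <- design_params()
  for (s in 1:3) {
    run <- make_run_timing(make_block_sequence(p, seed = s), p, seed = s + 10)
    tr <- simulate_trace(run, oculo_params(), seed = s + 20)
    qc <- qc_run(tr, run)
    expect_true(all(qc$valid), label = sprintf("seed %d all valid", s))
    expect_true(all(qc$n_events == 6))
  }
})

test_that("validate_block distinguishes the failure reasons", {
  run <- one_block_run("small", "left", seed = 1)
  blk <- run$blocks[1, ]
  ok_events <- data.frame(
    onset_s = blk$onset_s + blk$target_times_s[[1]] + 0.2,
    amplitude_deg = rep(5, 6),
    direction = rep(c("left", "right"), 3),
    class = rep("small", 6),
    peak_velocity_deg_s = 150)
  expect_true(validate_block(ok_events, blk)$valid)
  # one event only -> count_mismatch
  r <- validate_block(ok_events[1, ], blk)
  expect_false(r$valid); expect_equal(r$reason, "count_mismatch")
  # large classes in a small block -> class_mismatch
  bad <- ok_events; bad$class <- "large"; bad$amplitude_deg <- 30
  r <- validate_block(bad, blk)
  expect_false(r$valid); expect_equal(r$reason, "class_mismatch")
  # mirrored directions -> direction_mismatch
  bad <- ok_events; bad$direction <- rep(c("right", "left"), 3)
  r <- validate_block(bad, blk)
  expect_false(r$valid); expect_equal(r$reason, "direction_mismatch")
  # missing data dominates
  r <- validate_block(ok_events, blk, missing = TRUE)
  expect_equal(r$reason, "missing_data")
})

test_that("injected bad blocks are detected with the right reasons", {
  p <- design_params()
  run <- make_run_timing(make_block_sequence(p, seed = 9), p, seed = 9)
  bad <- data.frame(block = c(3, 7, 11),
                    mode = c("drop", "blink", "wrong_hemifield"))
  tr <- simulate_trace(run, oculo_params(), seed = 9, bad_blocks = bad)
  qc <- qc_run(tr, run)
  expect_equal(which(!qc$valid), c(3L, 7L, 11L))
  expect_equal(qc$reason[3], "count_mismatch")
  expect_equal(qc$reason[7], "missing_data")
  expect_equal(qc$reason[11], "direction_mismatch")
})

test_that("exclusion rules drop blocks, runs, and subjects at >50%", {
  mk <- function(subject, run, n_bad, n = 36) {
    data.frame(subject = subject, run = run, block = seq_len(n),
               valid = c(rep(FALSE, n_bad), rep(TRUE, n - n_bad)))
  }
  qc <- rbind(
    mk("s1", 1, 0), mk("s1", 2, 30),           # run 2: 30/36 bad -> run excluded
    mk("s2", 1, 24), mk("s2", 2, 24),          # 48/72 bad -> subject excluded
    mk("s3", 1, 2), mk("s3", 2, 0))            # kept, two blocks dropped
  rep <- apply_exclusions(qc)
  expect_equal(rep$excluded_subjects, "s2")
  expect_equal(rep$excluded_runs$subject, "s1")
  expect_equal(rep$excluded_runs$run, 2)
  expect_true(all(rep$retained$valid))
  expect_false(any(rep$retained$subject == "s2"))
  expect_false(any(rep$retained$subject == "s1" & rep$retained$run == 2))
  expect_equal(sum(rep$retained$subject == "s3"), 70)
  # all-valid dataset: nothing excluded
  rep0 <- apply_exclusions(rbind(mk("a", 1, 0), mk("b", 1, 0)))
  expect_length(rep0$excluded_subjects, 0)
  expect_equal(nrow(rep0$excluded_runs), 0)
  expect_equal(nrow(rep0$retained), 72)
})
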