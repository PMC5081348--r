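test_that("block sequences are balanced with near-uniform transitions", {
  p <- design_params()
  for (seed in 1:8) {
    sq <- make_block_sequence(p, seed = seed)
    expect_length(sq, 36)
    expect_true(all(table(sq) == 6))
    tc <- transition_counts(sq)
    # all 30 ordered cross-condition pairs occur, spread at most 1
    expect_length(tc, 30)
    expect_lte(max(tc) - min(tc), 1)
  }
})

test_that("degenerate sequence parameters behave as specified", {
  expect_error(make_block_sequence(design_params(repeats_per_condition = 0)),
               "repeats")
  p1 <- design_params(repeats_per_condition = 1)
  sq <- make_block_sequence(p1, seed = 3)
  expect_length(sq, 6)
  expect_true(all(table(sq) == 1))
})

test_that("sequences and timing are deterministic given the seed", {
  p <- design_params()
  expect_identical(make_block_sequence(p, seed = 11), make_block_sequence(p, seed = 11))
  r1 <- make_run_timing(make_block_sequence(p, seed = 2), p, seed = 9)
  r2 <- make_run_timing(make_block_sequence(p, seed = 2), p, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(
    make_run_timing(make_block_sequence(p, seed = 2), p, seed = 10), r1))
})

test_that("run timing obeys lead fixation, jitter bounds, and duration", {
  p <- design_params()
  sq <- make_block_sequence(p, seed = 4)
  run <- make_run_timing(sq, p, seed = 4)
  b <- run$blocks
  expect_equal(b$onset_s[1], 8.0)
  gaps <- b$onset_s[-1] - (b$onset_s[-36] + b$duration_s[-36])
  expect_true(all(gaps >= 6 & gaps <= 8))
  expect_true(all(diff(b$onset_s) > 0))
  expect_equal(run$duration_s, b$onset_s[36] + 4 + 8)
  expect_gte(run$duration_s, 36 * 4 + 35 * 6 + 16)
  expect_lte(run$duration_s, 36 * 4 + 35 * 8 + 16)
  expect_equal(run$n_volumes, ceiling(run$duration_s / 2))
  # single-block run: 8 + 4 + 8 seconds
  r1 <- make_run_timing(sq[1], p, seed = 1)
  expect_equal(r1$duration_s, 20)
})

test_that("target schedules alternate periphery and center at 1.5 Hz", {
  p <- design_params()
  for (cond in list(c("small", "left", -5), c("large", "right", 30))) {
    run <- one_block_run(cond[1], cond[2], seed = 8)
    tgt <- run$blocks$target_positions_deg[[1]]
    tms <- run$blocks$target_times_s[[1]]
    expect_length(tgt, 6)
    expect_true(all(tgt[c(2, 4, 6)] == 0))
    expect_true(all(tgt[c(1, 3, 5)] == as.numeric(cond[3])))
    expect_true(all(diff(tms) > 0))
    expect_true(all(tms >= 0 & tms < 4))
    expect_equal(length(tms) / 4, 1.5)  # 6 targets in 4 s
  }
  # mixed block: the three eccentricities, once each, same hemifield sign
  run <- one_block_run("mixed", "right", seed = 2)
  periph <- run$blocks$target_positions_deg[[1]][c(1, 3, 5)]
  expect_setequal(periph, c(5, 10, 30))
})

test_that("full designs count blocks and targets correctly", {
  p <- design_params()
  des <- make_experiment_design(p, seed = 6, runs = 2)
  expect_length(des$runs, 2)
  for (run in des$runs) {
    expect_equal(nrow(run$blocks), 36)
    expect_equal(sum(lengths(run$blocks$target_times_s)), 216)
  }
})

test_that("events TSV round-trips the block table", {
  p <- design_params()
  run <- make_run_timing(make_block_sequence(p, seed = 1), p, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(run, path)
  ev <- read_events_tsv(path)
  expect_equal(nrow(ev), 36)
  expect_equal(ev$onset, run$blocks$onset_s)
  expect_equal(ev$trial_type, run$blocks$size)
  expect_equal(ev$hemifield, run$blocks$hemifield)
})
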