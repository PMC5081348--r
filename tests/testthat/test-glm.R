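test_that("high-pass filter removes drift, keeps constants and block signal", {
  n <- 200; tr <- 2
  tt <- (seq_len(n) - 1) * tr
  # pure linear drift -> constant output (residual slope below 1e-6 of input)
  drift <- 0.5 * tt
  out <- gaussian_highpass(drift, 50, tr)
  expect_lt(max(abs(out - mean(drift))), 1e-6 * 0.5 * max(tt))
  # constant unchanged
  expect_equal(gaussian_highpass(rep(3, n), 50, tr), rep(3, n), tolerance = 1e-10)
  # block-frequency signal (~1/11 s period band) retains >= 90% amplitude:
  # measure the transfer on sinusoids bracketing the block rate
  for (period in c(8, 11, 22)) {
    sig <- sin(2 * pi * tt / period)
    flt <- gaussian_highpass(sig, 50, tr)
    gain <- sd(flt[20:180]) / sd(sig[20:180])  # interior, avoid edge effects
    expect_gt(gain, 0.90)
  }
})

test_that("design matrices have the documented column inventory", {
  p <- design_params()
  run <- make_run_timing(make_block_sequence(p, seed = 1), p, seed = 1)
  Xb <- build_design_matrix(run, glm_config(mode = "per_block"))
  expect_equal(ncol(Xb), 36 + 36 + 6 + 1)
  Xc <- build_design_matrix(run, glm_config(mode = "per_condition"))
  expect_equal(ncol(Xc), 6 + 6 + 6 + 1)
  # derivative columns integrate to ~0 for blocks whose kernel support is
  # fully inside the run (end-of-run blocks have truncated undershoots)
  interior <- which(run$blocks$onset_s < run$duration_s - 40)
  dsum <- colSums(Xb[, sprintf("deriv_block_%02d", interior), drop = FALSE])
  expect_lt(max(abs(dsum)), 0.05)
  # overlapping blocks rejected
  bad <- run
  bad$blocks$onset_s[2] <- bad$blocks$onset_s[1] + 1
  expect_error(build_design_matrix(bad, glm_config()), "overlapping")
})

test_that("OLS recovers noiseless betas exactly and flags rank problems", {
  p <- design_params(runs_per_subject = 1)
  des <- make_experiment_design(p, seed = 2, runs = 1)
  atlas <- build_atlas(sizes = c("L-SEF" = 25L), seed = 1)
  b0 <- simulate_subject(des, atlas,
                         effect_spec(pattern_effect = c(FEF = 0, Prec = 0,
                                                        SEF = 1.2, Par = 0),
                                     subject_scale_sd = 0),
                         noise = noise_config(sd = 0, baseline_sd = 0, drift_sd = 0),
                         seed = 3)
  run <- des$runs[[1]]
  X <- build_design_matrix(run, glm_config(mode = "per_block"))
  fit <- fit_glm(t(b0$runs[[1]]), X)
  expect_equal(fit$dropped_columns, paste0("motion_", 1:6))
  # injected per-block amplitude = amplitude column for that block's class
  blocks <- run$blocks
  truth_amp <- b0$truth$amplitudes
  for (bb in c(1, 10, 36)) {
    beta <- fit$betas[sprintf("block_%02d", bb), ]
    expect_equal(unname(beta), unname(truth_amp[, blocks$size[bb]]),
                 tolerance = 1e-6)
  }
  # duplicated column triggers a named rank-deficiency error
  Xdup <- cbind(X, dup = X[, 1])
  expect_error(fit_glm(t(b0$runs[[1]]), Xdup), "collinear")
})

test_that("beta RMSE scales linearly with noise SD", {
  p <- design_params(runs_per_subject = 1)
  atlas <- build_atlas(sizes = c("L-SEF" = 20L), seed = 1)
  eff <- effect_spec(pattern_effect = c(FEF = 0, Prec = 0, SEF = 1, Par = 0),
                     subject_scale_sd = 0)
  rmse_at <- function(sd, seeds) {
    vapply(seeds, function(s) {
      des <- make_experiment_design(p, seed = s, runs = 1)
      run <- des$runs[[1]]
      b <- simulate_subject(des, atlas, eff,
                            noise = noise_config(sd = sd, ar_rho = 0,
                                                 baseline_sd = 0, drift_sd = 0),
                            seed = s + 17)
      b0 <- simulate_subject(des, atlas, eff,
                             noise = noise_config(sd = 0, baseline_sd = 0,
                                                  drift_sd = 0),
                             seed = s + 17)
      X <- build_design_matrix(run, glm_config(mode = "per_block"))
      bl <- grep("^block_", colnames(X))
      err <- fit_glm(t(b$runs[[1]]), X)$betas[bl, ] -
             fit_glm(t(b0$runs[[1]]), X)$betas[bl, ]
      sqrt(mean(err^2))
    }, numeric(1))
  }
  seeds <- 1:20
  r <- vapply(c(0.5, 1, 2), rmse_at, numeric(length(seeds)), seeds = seeds)
  slope <- coef(lm(log(colMeans(r)) ~ log(c(0.5, 1, 2))))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("contrasts apply canonical weights correctly", {
  betas <- matrix(rnorm(6 * 10), 6, 10,
                  dimnames = list(c("large_left", "large_right", "small_left",
                                    "small_right", "mixed_left", "mixed_right"),
                                  NULL))
  w <- contrast_weights("large_vs_small")
  expect_equal(sum(w), 0)
  expect_equal(sum(contrast_weights("adaptation")), 0)
  cm <- compute_contrast(betas, w)
  expect_equal(cm, 0.5 * colSums(betas[1:2, ]) - 0.5 * colSums(betas[3:4, ]))
  # zero weights -> zero map; equal condition betas -> zero map
  expect_equal(compute_contrast(betas, w * 0), rep(0, 10))
  eq <- betas; eq[] <- rep(betas[1, ], each = 6)
  expect_equal(compute_contrast(eq, w), rep(0, 10), tolerance = 1e-12)
  expect_error(compute_contrast(betas, c(bogus = 1)), "not in betas")
  expect_error(compute_contrast(betas, rep(1, 4)), "length")
})

test_that("Gaussian smoothing preserves mass, DC, and the identity at 0", {
  g <- grid_spec(voxel_size_mm = c(3, 3, 3.3), dim_vox = c(21L, 21L, 21L))
  vol <- array(0, g$dim_vox)
  expect_identical(smooth_volume(vol, 0, g), vol)
  # delta input: kernel mass sums to 1
  vol[11, 11, 11] <- 1
  sm <- smooth_volume(vol, 5, g)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_lt(max(sm), 1)
  # constant volume unchanged (edge renormalization)
  cvol <- array(2.5, g$dim_vox)
  expect_equal(smooth_volume(cvol, 5, g), cvol, tolerance = 1e-10)
})
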