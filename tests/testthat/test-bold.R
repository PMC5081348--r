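test_that("double-gamma HRF has the canonical shape", {
  tg <- seq(0, 32, by = 0.01)
  h <- hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-6)
  pk <- tg[which.max(h)]
  expect_gt(pk, 4); expect_lt(pk, 6)
  expect_gt(sum(h) * 0.01, 0)           # positive integral
  expect_lt(min(h), 0)                  # undershoot present
})

test_that("noiseless single-block response is the boxcar-kernel convolution", {
  run <- one_block_run("small", "left", seed = 1)
  R <- saccdecode:::convolved_regressors(run, "blk")
  # independent oracle: direct Riemann-sum convolution of the 4 s boxcar
  # (onset 8 s) with the unit-peak kernel, evaluated at the volume times
  kern_t <- seq(0, 32, by = 0.01)
  kern <- hrf(kern_t)
  vol_t <- (seq_len(run$n_volumes) - 1) * run$tr_s
  expected <- vapply(vol_t, function(tv) {
    s <- kern_t[kern_t <= tv - 8 & kern_t >= tv - 12]
    sum(hrf(s)) * 0.01
  }, numeric(1))
  amp <- 2.5
  expect_equal(amp * drop(R), amp * expected, tolerance = 0.02)
  expect_equal(max(amp * R), amp * max(expected), tolerance = 0.02)
})

test_that("subject simulation is deterministic and ground truth is complete", {
  p <- design_params(runs_per_subject = 2)
  des <- make_experiment_design(p, seed = 3, runs = 2)
  atlas <- small_atlas(30, seed = 1)
  b1 <- simulate_subject(des, atlas, seed = 7)
  b2 <- simulate_subject(des, atlas, seed = 7)
  expect_identical(b1$runs, b2$runs)
  expect_equal(ncol(b1$runs[[1]]), des$runs[[1]]$n_volumes)
  expect_equal(nrow(b1$runs[[1]]), length(atlas$voxels))
  # ground truth reconstructs the noiseless signal exactly:
  # Y = amplitudes %*% t(regressors) + noise + 100, so subtracting the
  # reconstruction from two seeds differing only in pattern draw is not
  # needed -- instead verify with noise turned off
  b0 <- simulate_subject(des, atlas, noise = noise_config(sd = 0, baseline_sd = 0,
                                                          drift_sd = 0),
                         seed = 7)
  recon <- b0$truth$amplitudes %*% t(b0$truth$regressors[[1]]) + 100
  expect_equal(unname(b0$runs[[1]]), unname(recon), tolerance = 1e-10)
})

test_that("pattern effects are confined to informative ROI families", {
  p <- design_params(runs_per_subject = 2)
  des <- make_experiment_design(p, seed = 5, runs = 2)
  atlas <- small_atlas(30, seed = 2)
  eff <- effect_spec(pattern_effect = c(FEF = 1, Prec = 0, SEF = 0, Par = 2))
  b <- simulate_subject(des, atlas, eff, seed = 9)
  pat <- b$truth$patterns
  vox <- atlas$voxels
  for (m in atlas$masks) {
    idx <- match(m$voxels, vox)
    fam <- sub("^[LR]-", "", m$label)
    if (fam %in% c("SEF", "Prec")) {
      expect_true(all(pat[idx, ] == 0), label = paste(m$label, "uninformative"))
    } else {
      expect_gt(sum(pat[idx, ] != 0), 0)
      # unit-norm per class within each informative ROI
      for (cl in colnames(pat))
        expect_equal(sum(pat[idx, cl]^2), 1, tolerance = 1e-10)
    }
  }
  # informative fraction respected
  ninf <- sum(rowSums(pat != 0) > 0)
  expect_equal(ninf, 4 * round(0.3 * 30))
})

test_that("decoding accuracy increases with pattern effect", {
  # 3-point monotonicity, averaged over seeds, at desk scale
  p <- design_params(runs_per_subject = 2)
  atlas <- build_atlas(sizes = c("L-Par" = 40L), seed = 1)
  mean_acc <- function(pe) {
    mean(vapply(1:6, function(s) {
      des <- make_experiment_design(p, seed = s, runs = 2)
      b <- simulate_subject(des, atlas,
                            effect_spec(pattern_effect = c(FEF = 0, Prec = 0,
                                                           SEF = 0, Par = pe),
                                        subject_scale_sd = 0),
                            seed = s + 100)
      betas <- lapply(seq_along(des$runs), function(rr) {
        g <- saccdecode:::fit_run_glms(b$runs[[rr]], des$runs[[rr]],
                                       list(glm = glm_config()))
        g$block_betas
      })
      sizes <- lapply(des$runs, function(r) r$blocks$size)
      as.numeric(loro_accuracy(make_sample_set(betas, sizes)))
    }, numeric(1)))
  }
  a0 <- mean_acc(0); a1 <- mean_acc(1.5); a2 <- mean_acc(6)
  expect_lte(a0, a1 + 5)
  expect_lte(a1, a2 + 5)
  expect_gt(a2, 75)      # strong signal decodes well
  expect_lt(abs(a0 - 50), 12)  # no signal stays near chance
})
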