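test_that("one-sample and paired t statistics match hand computation", {
  r <- one_sample_t(c(55, 60, 65), 50)
  expect_equal(r$statistic, 10 / (5 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_false(r$degenerate)
  expect_equal(one_sample_t(rep(50, 5), 50)$statistic, 0)
  expect_true(one_sample_t(rep(50, 5), 50)$degenerate)
  expect_equal(one_sample_t(rnorm(17) + 50, 50)$df, 16)
  expect_error(one_sample_t(1, 0), "n >= 2")
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  d <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$statistic, Inf)
  expect_error(paired_t(1:3, 1:4), "length mismatch")
})

test_that("exhaustive sign-flip p matches the stated 3-subject example", {
  # single ROI, diffs {5,10,15}: only the all-positive pattern attains t_obs
  res <- signflip_maxt(matrix(c(55, 60, 65), ncol = 1),
                       inference_config(), method = "exhaustive")
  expect_equal(res$table$p_fwe, 1 / 8)
  expect_equal(res$method, "exhaustive")
})

test_that("all-chance input gives t = 0 and p >= 0.5 everywhere", {
  acc <- matrix(50, 6, 4)
  res <- signflip_maxt(acc, inference_config(), method = "exhaustive")
  expect_true(all(res$table$t_obs == 0))
  expect_true(all(res$table$p_fwe >= 0.5))
})

test_that("vectorized exhaustive enumeration matches the naive oracle", {
  set.seed(11)
  D <- matrix(rnorm(8 * 3, mean = 0.6), 8, 3)
  res <- signflip_maxt(D + 50, inference_config(), method = "exhaustive")
  ora <- maxt_exhaustive_oracle(D)
  expect_equal(res$table$t_obs, unname(ora$t_obs), tolerance = 1e-10)
  expect_equal(res$table$p_fwe, unname(ora$p_fwe), tolerance = 1e-12)
  expect_equal(sort(res$tmax), sort(ora$tmax), tolerance = 1e-10)
})

test_that("Monte-Carlo p agrees with exhaustive within binomial error", {
  set.seed(21)
  D <- matrix(rnorm(10 * 4, mean = 0.5, sd = 1), 10, 4)
  ex <- signflip_maxt(D + 50, inference_config(), method = "exhaustive")
  mc <- signflip_maxt(D + 50, inference_config(n_permutations = 10000, seed = 2),
                      method = "montecarlo")
  for (r in 1:4) {
    p <- ex$table$p_fwe[r]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mc$table$p_fwe[r] - p), 3 * se + 2e-4)
  }
})

test_that("max-t dominance: family-wise p never below uncorrected p", {
  for (s in 1:5) {
    set.seed(s)
    D <- matrix(rnorm(9 * 5, mean = 0.3), 9, 5)
    res <- signflip_maxt(D + 50, inference_config(n_permutations = 2000, seed = s),
                         method = "montecarlo")
    expect_true(all(res$table$p_fwe >= res$table$p_uncorrected - 1e-12))
  }
})

test_that("family-wise error is controlled under the global null", {
  # 400 null tables, correlated across ROIs; rejection rate near alpha
  set.seed(31)
  n_rej <- 0L
  n_tab <- 400L
  for (i in seq_len(n_tab)) {
    shared <- rnorm(17)
    acc <- 50 + sqrt(0.3) * shared + sqrt(0.7) * matrix(rnorm(17 * 8), 17, 8)
    res <- signflip_maxt(acc, inference_config(n_permutations = 1000, seed = i),
                         method = "montecarlo")
    if (any(res$table$significant)) n_rej <- n_rej + 1L
  }
  # binomial 3-sigma band around the nominal 0.05
  expect_lte(n_rej / n_tab, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tab))
})

test_that("voxelwise group contrast recovers a planted effect and clusters it", {
  atlas <- build_atlas(sizes = c("L-SEF" = 60L), seed = 2)
  mask <- atlas$masks[["L-SEF"]]
  set.seed(41)
  n_sub <- 14
  maps <- matrix(rnorm(n_sub * 60), n_sub, 60)
  planted <- select_connected <- 1:10   # first 10 canonical voxels
  maps[, planted] <- maps[, planted] + 2.2
  res <- group_voxel_contrast(maps, mask,
                              inference_config(n_permutations = 2000, seed = 3))
  expect_gte(length(intersect(res$survivors, planted)), 8)
  expect_true(all(res$p_fwe >= 1 / 2001 & res$p_fwe <= 1))
  expect_gt(res$critical_t, 2)  # stricter than uncorrected
  expect_true(length(res$clusters) >= 1)
  expect_setequal(unlist(res$clusters), res$survivors)
})
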