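# small synthetic sample set with a plantable signal
make_test_sset <- function(n_runs = 4, per_class = 6, nvox = 30,
                           effect = 0, seed = 1) {
  set.seed(seed)
  pattern <- rnorm(nvox)
  pattern <- pattern / sqrt(sum(pattern^2))
  X <- NULL; labs <- c(); runs <- c()
  for (r in seq_len(n_runs)) {
    for (cl in c(-1, 1)) {
      M <- matrix(rnorm(per_class * nvox), per_class, nvox) +
        matrix(cl * effect * pattern, per_class, nvox, byrow = TRUE) +
        rnorm(1, 0, 3)  # run offset
      X <- rbind(X, M)
      labs <- c(labs, rep(if (cl < 0) "small" else "large", per_class))
      runs <- c(runs, rep(r, per_class))
    }
  }
  structure(list(X = X, labels = factor(labs, levels = c("large", "small")),
                 run = runs, subject_id = "t"), class = "sample_set")
}

test_that("mean centering modes satisfy their definitions and invariance", {
  ss <- make_test_sset(3, 4, 20, effect = 1, seed = 2)
  sp <- mean_center(ss, "per_sample_spatial")
  expect_lt(max(abs(rowMeans(sp$X))), 1e-10)
  vr <- mean_center(ss, "per_voxel_run")
  for (r in unique(ss$run))
    expect_lt(max(abs(colMeans(vr$X[vr$run == r, ]))), 1e-10)
  bo <- mean_center(ss, "both")
  for (r in unique(ss$run))
    expect_lt(max(abs(colMeans(bo$X[bo$run == r, ]))), 1e-10)
  # adding a constant to all features of one run leaves centered data unchanged
  ss2 <- ss
  ss2$X[ss2$run == 2, ] <- ss2$X[ss2$run == 2, ] + 7.3
  for (mode in c("per_sample_spatial", "per_voxel_run", "both"))
    expect_equal(mean_center(ss2, mode)$X, mean_center(ss, mode)$X,
                 tolerance = 1e-10)
})

test_that("sample sets keep only small/large blocks, 12 per class per run", {
  p <- design_params(runs_per_subject = 2)
  des <- make_experiment_design(p, seed = 4, runs = 2)
  betas <- lapply(des$runs, function(r) matrix(rnorm(36 * 10), 36, 10))
  sizes <- lapply(des$runs, function(r) r$blocks$size)
  ss <- make_sample_set(betas, sizes)
  expect_equal(nrow(ss$X), 48)
  for (r in 1:2) {
    expect_equal(sum(ss$run == r & ss$labels == "small"), 12)
    expect_equal(sum(ss$run == r & ss$labels == "large"), 12)
  }
})

test_that("leave-one-run-out decodes planted signal and stays at chance on null", {
  strong <- make_test_sset(4, 6, 30, effect = 8, seed = 3)
  expect_equal(as.numeric(loro_accuracy(strong)), 100)
  accs <- vapply(1:25, function(s)
    as.numeric(loro_accuracy(make_test_sset(3, 6, 30, effect = 0, seed = s))),
    numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 1e-9)
  expect_error(loro_accuracy(make_test_sset(1, 6, 10)), "2 runs")
})

test_that("decoding accuracy is deterministic given the data", {
  ss <- make_test_sset(3, 6, 25, effect = 1, seed = 9)
  expect_identical(loro_accuracy(ss), loro_accuracy(ss))
})

test_that("feature selection ranks by training-run localizer with tie-break", {
  loc <- cbind(c(3, 1, 2, 5, 4), c(3, 1, 2, 5, 4), c(0, 0, 0, 0, 0))
  expect_equal(select_topk(loc, 2, train_runs = 1:2), c(4L, 5L))
  # the zero third column changes ranks when included
  expect_equal(select_topk(loc, 1, train_runs = 1:3), 4L)
  # ties broken by canonical (ascending index) order
  tied <- matrix(1, 4, 2)
  expect_equal(select_topk(tied, 2), c(1L, 2L))
  expect_equal(select_topk(tied, 4), 1:4)
  expect_error(select_topk(tied, 9), "exceeds")
})

test_that("feature selection never reads the held-out run", {
  ss <- make_test_sset(3, 6, 40, effect = 2, seed = 5)
  loc <- matrix(rnorm(40 * 3), 40, 3)
  # poisoning the held-out run's localizer column must not change the result
  for (held in 1:3) {
    loc2 <- loc
    loc2[, held] <- 1e6
    sel1 <- select_topk(loc, 10, train_runs = setdiff(1:3, held))
    sel2 <- select_topk(loc2, 10, train_runs = setdiff(1:3, held))
    expect_identical(sel1, sel2)
  }
})

test_that("feature-count grids follow the 200..900-plus-full-size rule", {
  cfg <- mvpa_config()
  expect_equal(feature_counts(564, cfg), c(200L, 300L, 400L, 500L, 564L))
  expect_equal(feature_counts(1043, cfg), seq(200L, 900L, 100L))
  expect_equal(feature_counts(900, cfg), seq(200L, 900L, 100L))
  expect_equal(feature_counts(150, cfg), 150L)
  ss <- make_test_sset(3, 4, 250, effect = 4, seed = 6)
  loc <- matrix(rnorm(250 * 3), 250, 3)
  cv <- accuracy_vs_size(ss, loc, cfg)
  expect_equal(cv$n_features, c(200L, 250L))
  expect_true(all(cv$accuracy_pct >= 0 & cv$accuracy_pct <= 100))
})
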