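#' MVPA configuration
#'
#' @param svm_C SVM regularization parameter (default 1).
#' @param centering `"both"` (spatial per sample, then per voxel within
#'   run; default), `"per_sample_spatial"`, or `"per_voxel_run"`.
#' @param feature_min,feature_cap,feature_step feature-selection count grid:
#'   `seq(feature_min, min(feature_cap, roi_size), feature_step)`, plus the
#'   full ROI size when it is below the cap (defaults 200, 900, 100).
#' @param seed seed (the decoder itself is deterministic; kept for
#'   config provenance).
#' @return list of class `mvpa_config`.
#' @export
mvpa_config <- function(svm_C = 1,
                        centering = c("both", "per_sample_spatial", "per_voxel_run"),
                        feature_min = 200L, feature_cap = 900L,
                        feature_step = 100L, seed = 1L) {
  assert_scalar_num(svm_C, "svm_C", lower = 1e-12)
  structure(list(svm_C = svm_C, centering = match.arg(centering),
                 feature_min = as.integer(feature_min),
                 feature_cap = as.integer(feature_cap),
                 feature_step = as.integer(feature_step),
                 seed = as.integer(seed)),
            class = "mvpa_config")
}

#' Assemble a decoding sample set from per-block betas
#'
#' Keeps only small- and large-saccade blocks (hemifields collapsed): with
#' the default design this yields 12 samples per condition per run.
#'
#' @param betas_by_run list (one per run) of block x voxel beta matrices.
#' @param sizes_by_run list (one per run) of per-block size labels matching
#'   the beta rows.
#' @param subject_id identifier.
#' @return list of class `sample_set`: `X` (samples x voxels), `labels`
#'   (factor small/large), `run` (integer), `subject_id`.
#' @export
make_sample_set <- function(betas_by_run, sizes_by_run, subject_id = "sub-01") {
  stopifnot(length(betas_by_run) == length(sizes_by_run))
  Xs <- list(); labs <- character(0); runs <- integer(0)
  for (rr in seq_along(betas_by_run)) {
    keep <- sizes_by_run[[rr]] %in% c("small", "large")
    Xs[[rr]] <- betas_by_run[[rr]][keep, , drop = FALSE]
    labs <- c(labs, sizes_by_run[[rr]][keep])
    runs <- c(runs, rep(rr, sum(keep)))
  }
  structure(list(X = do.call(rbind, Xs),
                 labels = factor(labs, levels = c("large", "small")),
                 run = runs, subject_id = subject_id),
            class = "sample_set")
}

#' Mean-center a sample set
#'
#' Applied independently within each run. `per_sample_spatial` subtracts
#' each sample's mean over voxels (removes image-wide signal changes);
#' `per_voxel_run` subtracts each voxel's mean over that run's samples
#' (removes session effects); `both` applies spatial then per-voxel
#' centering. Label-free, so it never leaks class information across runs.
#'
#' @param sset a `sample_set` (or plain matrix with `runs` supplied).
#' @param mode centering mode (see [mvpa_config()]).
#' @param runs run ids when `sset` is a bare matrix.
#' @return centered object of the same type.
#' @export
mean_center <- function(sset, mode = c("both", "per_sample_spatial", "per_voxel_run"),
                        runs = NULL) {
  mode <- match.arg(mode)
  bare <- is.matrix(sset)
  X <- if (bare) sset else sset$X
  rr <- if (bare) runs else sset$run
  stopifnot(length(rr) == nrow(X))
  if (mode %in% c("per_sample_spatial", "both"))
    X <- X - rowMeans(X)
  if (mode %in% c("per_voxel_run", "both")) {
    for (u in unique(rr)) {
      idx <- which(rr == u)
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                        colMeans(X[idx, , drop = FALSE]))
    }
  }
  if (bare) X else { sset$X <- X; sset }
}

#' Select the top-k voxels by a training-only localizer
#'
#' Ranks voxels by the mean all-saccades-greater-than-rest parameter
#' estimate over the training runs; ties break by canonical voxel order
#' (lower index first).
#'
#' @param localizer voxel x run matrix of per-run localizer estimates.
#' @param k number of voxels to keep.
#' @param train_runs column indices of the training runs.
#' @return integer vector of k voxel indices (ascending canonical order).
#' @export
select_topk <- function(localizer, k, train_runs = seq_len(ncol(localizer))) {
  nvox <- nrow(localizer)
  if (k > nvox) stopf("invalid parameter: k (%d) exceeds ROI size (%d)", k, nvox)
  score <- rowMeans(localizer[, train_runs, drop = FALSE])
  ord <- order(-score, seq_len(nvox))
  sort(ord[seq_len(k)])
}

#' Leave-one-run-out cross-validated decoding accuracy
#'
#' For each fold, the held-out run's samples are never touched during
#' training: centering is per-run (label-free), feature selection uses the
#' training runs' localizer only, and the SVM sees training rows only. The
#' per-subject score is the mean over folds of the percentage of held-out
#' samples labelled correctly.
#'
#' @param sset a `sample_set`.
#' @param config an [mvpa_config()].
#' @param localizer optional voxel x run localizer matrix (required when
#'   `k` is given).
#' @param k optional feature count for [select_topk()].
#' @return mean accuracy in percent. Attribute `fold_accuracy` holds the
#'   per-fold values.
#' @export
loro_accuracy <- function(sset, config = mvpa_config(), localizer = NULL, k = NULL) {
  runs <- unique(sset$run)
  if (length(runs) < 2) stopf("invalid parameter: need >= 2 runs for cross-validation")
  cs <- mean_center(sset, config$centering)
  acc <- vapply(runs, function(held) {
    tr <- cs$run != held
    cols <- if (!is.null(k)) {
      if (is.null(localizer)) stopf("feature selection requires a localizer")
      select_topk(localizer, k, train_runs = which(runs != held))
    } else seq_len(ncol(cs$X))
    fit <- train_linear_svm(cs$X[tr, cols, drop = FALSE], cs$labels[tr],
                            C = config$svm_C)
    pred <- predict(fit, cs$X[!tr, cols, drop = FALSE])
    mean(pred$label == as.character(cs$labels[!tr])) * 100
  }, numeric(1))
  out <- mean(acc)
  attr(out, "fold_accuracy") <- acc
  out
}

#' Feature-count grid for an ROI
#'
#' @param roi_size voxel count of the ROI.
#' @param config an [mvpa_config()].
#' @return integer vector of feature counts.
#' @export
feature_counts <- function(roi_size, config = mvpa_config()) {
  top <- min(config$feature_cap, roi_size)
  if (top < config$feature_min) return(as.integer(roi_size))
  counts <- seq(config$feature_min, top, by = config$feature_step)
  if (roi_size <= config$feature_cap && !(roi_size %in% counts))
    counts <- c(counts, roi_size)
  as.integer(counts)
}

#' Decoding accuracy as a function of feature-set size
#'
#' Runs [loro_accuracy()] at each count of [feature_counts()].
#'
#' @param sset a `sample_set`.
#' @param localizer voxel x run localizer matrix.
#' @param config an [mvpa_config()].
#' @return data.frame with `n_features`, `accuracy_pct`.
#' @export
accuracy_vs_size <- function(sset, localizer, config = mvpa_config()) {
  counts <- feature_counts(ncol(sset$X), config)
  data.frame(
    n_features = counts,
    accuracy_pct = vapply(counts, function(k)
      as.numeric(loro_accuracy(sset, config, localizer = localizer, k = k)),
      numeric(1)))
}
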