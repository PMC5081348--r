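#' First-level GLM configuration
#'
#' @param highpass_sigma_s Gaussian running-line high-pass sigma (50 s).
#' @param temporal_derivatives include a temporal derivative per task
#'   regressor (default TRUE).
#' @param n_motion number of motion regressor columns (default 6;
#'   zero-filled when no motion table is supplied).
#' @param mode `"per_block"` (one regressor per block; beta-series for the
#'   MVPA) or `"per_condition"` (one per block type; univariate branch).
#' @param smoothing_fwhm_mm spatial smoothing for the univariate branch
#'   (default 5 mm).
#' @return list of class `glm_config`.
#' @export
glm_config <- function(highpass_sigma_s = 50, temporal_derivatives = TRUE,
                       n_motion = 6L, mode = c("per_block", "per_condition"),
                       smoothing_fwhm_mm = 5) {
  assert_scalar_num(highpass_sigma_s, "highpass_sigma_s", lower = 1e-9)
  mode <- match.arg(mode)
  structure(list(highpass_sigma_s = highpass_sigma_s,
                 temporal_derivatives = isTRUE(temporal_derivatives),
                 n_motion = as.integer(n_motion), mode = mode,
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "glm_config")
}

#' Gaussian-weighted running-line high-pass filter
#'
#' At each time point the value of a local straight-line fit with Gaussian
#' weights (SD = `sigma_s`) centered there is subtracted; the series mean is
#' added back. A pure linear drift is removed exactly; a constant series is
#' unchanged; block-frequency signal passes nearly unattenuated.
#'
#' @param series numeric vector, or a time x series matrix filtered
#'   column-wise.
#' @param sigma_s filter sigma in seconds (default 50).
#' @param tr sampling interval in seconds (default 2).
#' @return filtered vector/matrix of the same shape.
#' @export
gaussian_highpass <- function(series, sigma_s = 50, tr = 2) {
  y <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  n <- nrow(y)
  if (n < 3) stopf("invalid parameter: series length must be >= 3")
  H <- highpass_hat_matrix(n, sigma_s, tr)
  mu <- colMeans(y)
  out <- y - H %*% y
  out <- sweep(out, 2, mu, "+")
  if (is.matrix(series)) out else drop(out)
}

# hat matrix of the Gaussian-weighted local linear fit (n x n); row i gives
# the fitted value at time i as a linear functional of the series
highpass_hat_matrix <- function(n, sigma_s, tr) {
  tt <- (seq_len(n) - 1) * tr
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- dnorm(tt - tt[i], sd = sigma_s)
    d <- tt - tt[i]
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    det <- s0 * s2 - s1^2
    # fitted value at d = 0 of weighted least-squares line a + b*d
    H[i, ] <- (s2 * w - s1 * w * d) / det
  }
  H
}

#' Build a first-level design matrix
#'
#' Regressors are boxcars convolved with the double-gamma HRF on a 0.1 s
#' grid, sampled at volume times. `per_block` mode yields one regressor per
#' block (beta series); `per_condition` one per block type. Temporal
#' derivatives (first difference of the fine-grid convolution) follow the
#' task columns, then `n_motion` motion columns (zeros unless a motion
#' table is given), then the intercept. For the default 36-block run:
#' 36 + 36 + 6 + 1 = 79 columns; per-condition: 6 + 6 + 6 + 1 = 19.
#'
#' @param run a `run_design`.
#' @param config a [glm_config()].
#' @param n_volumes number of volumes (default `run$n_volumes`).
#' @param hrfp an [hrf_params()].
#' @param motion optional `n_volumes x n_motion` matrix of motion estimates.
#' @return matrix with column names; attribute `labels` marks the role of
#'   each column (`block_*`/condition labels, `deriv_*`, `motion_*`,
#'   `intercept`).
#' @export
build_design_matrix <- function(run, config = glm_config(),
                                n_volumes = run$n_volumes,
                                hrfp = hrf_params(), motion = NULL) {
  b <- run$blocks
  if (any(diff(b$onset_s) < b$duration_s[-nrow(b)]))
    stopf("invalid design: overlapping blocks")
  classes <- if (config$mode == "per_block") {
    sprintf("block_%02d", b$index)
  } else {
    b$condition
  }
  dt <- 0.1
  nv <- n_volumes
  run2 <- run
  run2$n_volumes <- nv
  X <- convolved_regressors(run2, classes, hrfp, dt = dt)
  labels <- colnames(X)
  if (config$temporal_derivatives) {
    D <- convolved_regressors(run2, classes, hrfp, dt = dt, derivative = TRUE)
    colnames(D) <- paste0("deriv_", colnames(D))
    X <- cbind(X, D)
    labels <- c(labels, colnames(D))
  }
  if (config$n_motion > 0) {
    M <- if (is.null(motion)) matrix(0, nv, config$n_motion) else {
      stopifnot(nrow(motion) == nv, ncol(motion) == config$n_motion)
      as.matrix(motion)
    }
    colnames(M) <- paste0("motion_", seq_len(config$n_motion))
    X <- cbind(X, M)
    labels <- c(labels, colnames(M))
  }
  X <- cbind(X, intercept = 1)
  labels <- c(labels, "intercept")
  attr(X, "labels") <- labels
  X
}

#' Fit a voxel-wise ordinary least squares GLM
#'
#' All-zero columns (e.g. zero-filled motion regressors) are dropped from
#' the fit and reported with coefficient 0; any remaining rank deficiency
#' raises an error naming the collinear columns. Prewhitening is
#' deliberately not performed (OLS only): at these block frequencies mild
#' AR(1) noise biases variance, not coefficient, estimates, and group
#' inference downstream is a summary-statistics model robust to first-level
#' variance misestimation.
#'
#' @param Y time x voxel data matrix (or a `bold_subject` run transposed by
#'   the caller).
#' @param X design matrix from [build_design_matrix()].
#' @return list of class `glm_fit`: `betas` (coefficient x voxel matrix,
#'   rows in design-column order), `resid_var` per voxel, `df`,
#'   `dropped_columns`.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stopf("volumes (%d) do not match design matrix rows (%d)", nrow(Y), nrow(X))
  zero_cols <- which(colSums(abs(X)) == 0)
  keep <- setdiff(seq_len(ncol(X)), zero_cols)
  Xk <- X[, keep, drop = FALSE]
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qx$pivot[(qx$rank + 1):ncol(Xk)]]
    stopf("rank-deficient design matrix; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  beta_k <- qr.coef(qx, Y)
  res <- Y - Xk %*% beta_k
  df <- nrow(Y) - qx$rank
  betas <- matrix(0, ncol(X), ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
  betas[keep, ] <- beta_k
  structure(list(betas = betas,
                 resid_var = colSums(res^2) / df,
                 df = df,
                 dropped_columns = colnames(X)[zero_cols]),
            class = "glm_fit")
}

#' Canonical contrast weight sets
#'
#' `large_vs_small`: (+1/2, +1/2, -1/2, -1/2, 0, 0) over
#' (large_left, large_right, small_left, small_right, mixed_left,
#' mixed_right). `adaptation` (mixed minus same-size):
#' (-1/4, -1/4, -1/4, -1/4, +1/2, +1/2).
#'
#' @param name `"large_vs_small"` or `"adaptation"`.
#' @return named numeric weight vector over the six condition labels.
#' @export
contrast_weights <- function(name = c("large_vs_small", "adaptation")) {
  name <- match.arg(name)
  switch(name,
    large_vs_small = c(large_left = 0.5, large_right = 0.5,
                       small_left = -0.5, small_right = -0.5,
                       mixed_left = 0, mixed_right = 0),
    adaptation = c(large_left = -0.25, large_right = -0.25,
                   small_left = -0.25, small_right = -0.25,
                   mixed_left = 0.5, mixed_right = 0.5))
}

#' Compute a voxel-wise contrast from per-condition betas
#'
#' @param betas condition x voxel matrix (rownames = condition labels).
#' @param weights named numeric vector over the conditions.
#' @return numeric voxel vector.
#' @export
compute_contrast <- function(betas, weights) {
  if (is.null(names(weights))) {
    if (length(weights) != nrow(betas))
      stopf("weights length (%d) != condition count (%d)",
            length(weights), nrow(betas))
    w <- weights
  } else {
    miss <- setdiff(names(weights), rownames(betas))
    if (length(miss))
      stopf("weights name(s) not in betas: %s", paste(miss, collapse = ", "))
    w <- numeric(nrow(betas))
    w[match(names(weights), rownames(betas))] <- weights
  }
  drop(crossprod(betas, w))
}

#' Separable 3-D Gaussian smoothing
#'
#' SD per axis is `fwhm / 2.3548` mm converted to voxels; the kernel is
#' truncated at 3 SD and edge-renormalized (convolving a constant volume
#' returns it unchanged). `fwhm = 0` is the identity.
#'
#' @param volume 3-D array.
#' @param fwhm_mm full width at half maximum, mm.
#' @param grid a [grid_spec()] supplying voxel dimensions.
#' @return smoothed array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm, grid = grid_spec()) {
  if (fwhm_mm < 0) stopf("invalid parameter: fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  stopifnot(length(dim(volume)) == 3)
  out <- volume
  norm <- array(1, dim(volume))
  for (ax in 1:3) {
    sd_vox <- (fwhm_mm / 2.3548) / grid$voxel_size_mm[ax]
    r <- max(1L, ceiling(3 * sd_vox))
    w <- dnorm(seq(-r, r), sd = sd_vox)
    w <- w / sum(w)
    out <- conv_axis(out, w, ax)
    norm <- conv_axis(norm, w, ax)
  }
  out / norm
}

# zero-padded 1-D convolution along one axis of a 3-D array, via shifted
# whole-array adds (vectorized; kernel length is small)
conv_axis <- function(a, w, axis) {
  d <- dim(a)
  r <- (length(w) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  for (s in seq_along(w)) {
    off <- s - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + w[s] * a[idx_src, , ]
    else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + w[s] * a[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + w[s] * a[, , idx_src]
  }
  out
}
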