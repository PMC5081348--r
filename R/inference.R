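#' Group inference configuration
#'
#' @param alpha family-wise error level (default 0.05).
#' @param n_permutations Monte-Carlo sign-flip draws (default 10000).
#' @param chance_pct theoretical chance accuracy (default 50).
#' @param exhaustive_max subject count at or below which the sign-flip null
#'   is enumerated exhaustively (all `2^n` patterns; default 12, allowed up
#'   to 20).
#' @param seed seed for the Monte-Carlo draws.
#' @return list of class `inference_config`.
#' @export
inference_config <- function(alpha = 0.05, n_permutations = 10000L,
                             chance_pct = 50, exhaustive_max = 12L,
                             seed = 1L) {
  assert_scalar_num(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (n_permutations < 1) stopf("invalid parameter: permutations >= 1 required")
  if (exhaustive_max > 20) stopf("invalid parameter: exhaustive_max above 20")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 chance_pct = chance_pct, exhaustive_max = as.integer(exhaustive_max),
                 seed = as.integer(seed)),
            class = "inference_config")
}

#' One-sample Student t statistic
#'
#' `t = mean(x - mu0) / (sd(x) / sqrt(n))`, df = n - 1. Zero sample
#' variance is signalled as a degenerate case with the `t = ±Inf`
#' convention (0 when the mean equals `mu0` exactly).
#'
#' @param values numeric vector, length >= 2.
#' @param mu0 null mean.
#' @return list: `statistic`, `df`, `degenerate`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) stopf("invalid parameter: need n >= 2")
  m <- mean(values) - mu0
  s <- sd(values)
  if (s == 0) {
    return(list(statistic = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1, degenerate = TRUE))
  }
  list(statistic = m / (s / sqrt(n)), df = n - 1, degenerate = FALSE)
}

#' Paired t test statistic (differences against zero)
#'
#' @param values_a,values_b equal-length numeric vectors.
#' @return list as for [one_sample_t()].
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stopf("invalid parameter: length mismatch (%d vs %d)",
          length(values_a), length(values_b))
  one_sample_t(values_a - values_b, 0)
}

# vectorized sign-flip t statistics: S is perms x n sign matrix, d the
# subject effect vector; squares are flip-invariant so only the mean moves
flip_t <- function(S, d) {
  n <- length(d)
  mP <- (S %*% d) / n
  vP <- (sum(d^2) - n * mP^2) / (n - 1)
  vP[vP < 0] <- 0
  tP <- mP / sqrt(vP / n)
  tP[vP == 0 & mP == 0] <- 0
  tP[vP == 0 & mP > 0] <- Inf
  tP[vP == 0 & mP < 0] <- -Inf
  drop(tP)
}

#' Sign-flip maximum-t permutation test across ROIs
#'
#' Tests each ROI's mean accuracy against chance while controlling the
#' family-wise error rate across ROIs: per permutation, one sign per
#' subject is drawn and shared across all ROIs (preserving the inter-ROI
#' correlation structure, required for a valid max-statistic correction),
#' the one-sample t is recomputed per ROI, and the maximum over ROIs is
#' recorded. Family-wise p per ROI is `(1 + #\{t_max >= t_obs\}) / (n_perm
#' + 1)` in Monte-Carlo mode; exhaustive mode enumerates all `2^n` sign
#' patterns and uses the exact `#\{>=\} / 2^n` convention. Per-ROI
#' uncorrected permutation p-values (same flips, per-ROI null) are also
#' returned, since reported p-values in this literature do not always state
#' which convention they follow.
#'
#' @param accuracy subjects x ROIs matrix (percent correct).
#' @param config an [inference_config()].
#' @param method `"auto"` (exhaustive when `n <= exhaustive_max`),
#'   `"exhaustive"`, or `"montecarlo"`.
#' @return list of class `permutation_result`: `table` (data.frame `roi`,
#'   `t_obs`, `p_fwe`, `p_uncorrected`, `significant`), `critical_t`
#'   (the `1 - alpha` quantile of the max-t null), `tmax` (null sample),
#'   `method`, `df`, `alpha`.
#' @export
signflip_maxt <- function(accuracy, config = inference_config(),
                          method = c("auto", "exhaustive", "montecarlo")) {
  accuracy <- as.matrix(accuracy)
  n <- nrow(accuracy)
  R <- ncol(accuracy)
  if (n < 2 || R < 1) stopf("invalid parameter: need >= 2 subjects and >= 1 ROI")
  method <- match.arg(method)
  if (method == "auto")
    method <- if (n <= config$exhaustive_max) "exhaustive" else "montecarlo"
  D <- accuracy - config$chance_pct
  t_obs <- vapply(seq_len(R), function(r) one_sample_t(D[, r])$statistic, numeric(1))
  S <- if (method == "exhaustive") {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    with_seed(config$seed,
              matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
                     ncol = n))
  }
  Tm <- vapply(seq_len(R), function(r) flip_t(S, D[, r]),
               numeric(nrow(S)))
  if (R == 1) Tm <- matrix(Tm, ncol = 1)
  tmax <- do.call(pmax, as.data.frame(Tm))
  np <- nrow(S)
  eps <- 1e-10
  if (method == "exhaustive") {
    p_fwe <- vapply(t_obs, function(t0) mean(tmax >= t0 - eps), numeric(1))
    p_unc <- vapply(seq_len(R), function(r) mean(Tm[, r] >= t_obs[r] - eps), numeric(1))
  } else {
    p_fwe <- vapply(t_obs, function(t0) (1 + sum(tmax >= t0 - eps)) / (np + 1), numeric(1))
    p_unc <- vapply(seq_len(R), function(r)
      (1 + sum(Tm[, r] >= t_obs[r] - eps)) / (np + 1), numeric(1))
  }
  crit <- as.numeric(quantile(tmax, 1 - config$alpha, type = 1, names = FALSE))
  roi <- colnames(accuracy) %||% paste0("roi", seq_len(R))
  structure(list(
    table = data.frame(roi = roi, t_obs = t_obs, p_fwe = p_fwe,
                       p_uncorrected = p_unc,
                       significant = p_fwe <= config$alpha,
                       stringsAsFactors = FALSE),
    critical_t = crit, tmax = tmax, method = method, df = n - 1,
    alpha = config$alpha),
    class = "permutation_result")
}

#' Voxel-wise group contrast with within-ROI max-t correction
#'
#' One-sample t across subjects per in-ROI voxel; family-wise correction
#' within the ROI by sign-flip max-t over that ROI's voxels (flips shared
#' across voxels), one-sided (positive contrast). Survivors are grouped
#' into 6-connected clusters.
#'
#' @param maps subjects x voxels matrix of contrast values.
#' @param mask the ROI mask (element of `atlas$masks`) supplying voxel
#'   coordinates for clustering; `NULL` skips clustering.
#' @param config an [inference_config()].
#' @return list of class `voxel_contrast_result`: `t` per voxel,
#'   `critical_t`, `p_fwe` per voxel, `survivors` (voxel column indices),
#'   `clusters` (list of survivor index vectors), `alpha`.
#' @export
group_voxel_contrast <- function(maps, mask = NULL, config = inference_config()) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  V <- ncol(maps)
  t_obs <- vapply(seq_len(V), function(v) one_sample_t(maps[, v])$statistic, numeric(1))
  np <- config$n_permutations
  chunk <- 2000L
  tmax <- numeric(0)
  done <- 0L
  pseed <- config$seed
  while (done < np) {
    nb <- min(chunk, np - done)
    S <- with_seed(derive_seed(pseed, 31L, done),
                   matrix(sample(c(-1, 1), nb * n, replace = TRUE), ncol = n))
    M1 <- (S %*% maps) / n
    ss <- matrix(colSums(maps^2), nb, V, byrow = TRUE)
    vP <- (ss - n * M1^2) / (n - 1)
    vP[vP <= 0] <- Inf
    Tp <- M1 / sqrt(vP / n)
    tmax <- c(tmax, apply(Tp, 1, max))
    done <- done + nb
  }
  eps <- 1e-10
  p_fwe <- vapply(t_obs, function(t0) (1 + sum(tmax >= t0 - eps)) / (np + 1), numeric(1))
  crit <- as.numeric(quantile(tmax, 1 - config$alpha, type = 1, names = FALSE))
  surv <- which(p_fwe <= config$alpha)
  clusters <- list()
  if (length(surv) > 0 && !is.null(mask)) {
    ijk <- mask$ijk[surv, , drop = FALSE]
    clusters <- connected_clusters(ijk)
    clusters <- lapply(clusters, function(ix) surv[ix])
  } else if (length(surv) > 0) {
    clusters <- list(surv)
  }
  structure(list(t = t_obs, critical_t = crit, p_fwe = p_fwe,
                 survivors = surv, clusters = clusters, alpha = config$alpha),
            class = "voxel_contrast_result")
}

# label 6-connected components of a set of ijk voxel coordinates (BFS)
connected_clusters <- function(ijk) {
  nv <- nrow(ijk)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  lookup <- seq_len(nv)
  names(lookup) <- key
  comp <- rep(0L, nv)
  cid <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (v in seq_len(nv)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (o in seq_len(6)) {
        nb <- lookup[paste(ijk[cur, 1] + offs[o, 1],
                           ijk[cur, 2] + offs[o, 2],
                           ijk[cur, 3] + offs[o, 3])]
        if (!is.na(nb) && comp[nb] == 0L) {
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }
  split(seq_len(nv), comp)
}
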