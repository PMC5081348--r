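#' Double-gamma hemodynamic response function parameters
#'
#' Canonical difference-of-gammas impulse response: peak at ~5 s, undershoot
#' near 16 s, peak:undershoot ratio 6, 32 s kernel.
#'
#' @param peak_delay_s,undershoot_delay_s gamma means (6, 16 s).
#' @param peak_dispersion,undershoot_dispersion gamma scales (1, 1).
#' @param ratio peak:undershoot amplitude ratio (6).
#' @param length_s kernel support (32 s).
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       ratio = 6, length_s = 32) {
  structure(as.list(environment()), class = "hrf_params")
}

#' Evaluate the double-gamma HRF
#'
#' Difference of two gamma densities (shape = delay/dispersion,
#' scale = dispersion), scaled so the kernel peak is 1. `hrf(0) = 0`
#' because both shapes exceed 1.
#'
#' @param t time points in seconds (`>= 0`).
#' @param params an [hrf_params()] object.
#' @return numeric vector of kernel values.
#' @export
hrf <- function(t, params = hrf_params()) {
  p <- params
  h <- dgamma(t, shape = p$peak_delay_s / p$peak_dispersion,
              scale = p$peak_dispersion) -
       dgamma(t, shape = p$undershoot_delay_s / p$undershoot_dispersion,
              scale = p$undershoot_dispersion) / p$ratio
  hs <- dgamma(seq(0, p$length_s, by = 0.05),
               shape = p$peak_delay_s / p$peak_dispersion,
               scale = p$peak_dispersion) -
        dgamma(seq(0, p$length_s, by = 0.05),
               shape = p$undershoot_delay_s / p$undershoot_dispersion,
               scale = p$undershoot_dispersion) / p$ratio
  h / max(hs)
}

#' Effect specification for the BOLD simulator
#'
#' Controls the multivoxel ground truth injected per ROI family. Each
#' subject draws, once, a unit-norm pattern vector per amplitude class
#' (small, large, medium) over a random `informative_fraction` of each
#' informative ROI's voxels. A block of class `c` adds
#' `(common_effect + pattern_effect * pattern_c[v])` per voxel to the
#' HRF-convolved boxcar; mixed blocks use the mean of the three patterns
#' (`mixed_rule = "mean"`). The per-family `pattern_effect` defaults are
#' calibrated so the default simulation reproduces the qualitative ROI
#' dissociation (parietal strongly decodable, FEF weakly, SEF/Prec at
#' chance); see the methods vignette.
#'
#' @param pattern_effect named amplitude (signal units) per ROI family
#'   (`FEF`, `Prec`, `SEF`, `Par`); 0 = uninformative.
#' @param common_effect all-saccades activation amplitude (default 1).
#' @param informative_fraction share of voxels carrying pattern (0.3).
#' @param mixed_rule `"mean"` (only rule implemented; kept as a field so the
#'   ground-truth record is self-describing).
#' @param adaptation_gain attenuation of the common effect for same-size
#'   (small/large) blocks relative to mixed blocks; default 0 (off).
#' @param subject_scale_sd between-subject SD of a multiplicative effect
#'   scale (mean 1, truncated at 0.2); gives group t-statistics realistic
#'   between-subject variance. Default 0.25.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(pattern_effect = c(FEF = 0.25, Prec = 0, SEF = 0, Par = 0.4),
                        common_effect = 1,
                        informative_fraction = 0.3,
                        mixed_rule = "mean",
                        adaptation_gain = 0,
                        subject_scale_sd = 0.25) {
  if (any(pattern_effect < 0) || common_effect < 0)
    stopf("invalid parameter: effect amplitudes must be >= 0")
  if (informative_fraction < 0 || informative_fraction > 1)
    stopf("invalid parameter: informative_fraction outside [0, 1]")
  if (!identical(mixed_rule, "mean"))
    stopf("invalid parameter: only mixed_rule = 'mean' is implemented")
  structure(as.list(environment()), class = "effect_spec")
}

#' Noise configuration for the BOLD simulator
#'
#' AR(1) temporal noise (marginal SD `sd`, lag-1 correlation `ar_rho`) plus
#' a run-specific baseline offset and linear drift, on top of a constant
#' grand mean of 100.
#'
#' @param sd marginal noise SD in signal units (default 1).
#' @param ar_rho AR(1) coefficient (default 0.3).
#' @param baseline_sd SD of the per-run baseline offset (default 2).
#' @param drift_sd SD of the per-run total linear drift excursion (default 2).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(sd = 1, ar_rho = 0.3, baseline_sd = 2, drift_sd = 2) {
  assert_scalar_num(sd, "sd", lower = 0)
  assert_scalar_num(ar_rho, "ar_rho", lower = -0.999, upper = 0.999)
  structure(as.list(environment()), class = "noise_config")
}

roi_family <- function(label) sub("^[LR]-", "", label)

#' Class-wise HRF-convolved regressor time courses for a run
#'
#' @param run a `run_design`.
#' @param classes character vector of block grouping labels (one per block).
#' @param hrfp an [hrf_params()] object.
#' @param dt fine convolution grid step (default 0.1 s).
#' @return matrix `n_volumes x n_classes` of regressor values sampled at
#'   volume acquisition times `(0:(nv-1)) * TR`.
#' @keywords internal
convolved_regressors <- function(run, classes, hrfp = hrf_params(), dt = 0.1,
                                 derivative = FALSE) {
  nv <- run$n_volumes
  tr <- run$tr_s
  kern <- hrf(seq(0, hrfp$length_s, by = dt), hrfp)
  vol_idx <- round((seq_len(nv) - 1) * tr / dt) + 1L
  ulab <- unique(classes)
  out <- matrix(0, nv, length(ulab), dimnames = list(NULL, ulab))
  # all blocks of one duration share a single canonical boxcar response,
  # shifted to each onset; this avoids one FFT per block
  curves <- new.env()
  curve_for <- function(duration) {
    key <- format(duration, digits = 12)
    if (!is.null(curves[[key]])) return(curves[[key]])
    nb <- max(1L, round(duration / dt))
    cv <- convolve(c(rep(1, nb), numeric(length(kern))), rev(kern),
                   type = "open")[seq_len(nb + length(kern))] * dt
    if (derivative) cv <- c(0, diff(cv)) / dt
    curves[[key]] <- cv
    cv
  }
  for (b in seq_len(nrow(run$blocks))) {
    cv <- curve_for(run$blocks$duration_s[b])
    off <- round(run$blocks$onset_s[b] / dt)
    rel <- vol_idx - off
    ok <- rel >= 1L & rel <= length(cv)
    u <- match(classes[b], ulab)
    out[ok, u] <- out[ok, u] + cv[rel[ok]]
  }
  out
}

#' Simulate one subject's multi-run BOLD data with known ground truth
#'
#' Generates, for every ROI voxel, the HRF-convolved block response with the
#' injected amplitude code of [effect_spec()], plus AR(1) noise, run
#' baseline offsets, linear drift, and a grand mean of 100. Only atlas
#' voxels are simulated (desk-scale memory); `n_background` optional pure
#' noise voxels can be appended. Deterministic given the seed; the returned
#' ground truth suffices to recompute the noiseless signal exactly.
#'
#' @param design an `experiment_design`.
#' @param atlas a `roi_atlas`.
#' @param effects an [effect_spec()].
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param n_background extra non-ROI noise voxels (default 0).
#' @return list of class `bold_subject`: `runs` (list of voxel x volume
#'   matrices, rownames = linear voxel indices), `truth` (patterns,
#'   informative voxel indices, subject scale, amplitude matrices per run,
#'   regressor time courses), `atlas`, `design`.
#' @export
simulate_subject <- function(design, atlas, effects = effect_spec(),
                             noise = noise_config(), seed = 1L,
                             n_background = 0L) {
  vox <- atlas$voxels
  nvx <- length(vox)
  roi_of <- rep(NA_character_, nvx)
  for (m in atlas$masks)
    roi_of[match(m$voxels, vox)] <- m$label
  classes_of_vox <- c("small", "large", "medium")
  with_seed(seed, {
    subj_scale <- max(0.2, rnorm(1, 1, effects$subject_scale_sd))
    patterns <- matrix(0, nvx, 3, dimnames = list(NULL, classes_of_vox))
    informative <- integer(0)
    for (m in atlas$masks) {
      fam <- roi_family(m$label)
      pe <- effects$pattern_effect[[fam]] %||% 0
      if (pe <= 0) next
      idx <- match(m$voxels, vox)
      ninf <- max(1L, round(effects$informative_fraction * m$size))
      inf_idx <- sort(sample(idx, ninf))
      informative <- c(informative, inf_idx)
      for (cl in classes_of_vox) {
        v <- rnorm(ninf)
        patterns[inf_idx, cl] <- patterns[inf_idx, cl] + v / sqrt(sum(v^2))
      }
    }
    pe_vox <- vapply(roi_of, function(l) effects$pattern_effect[[roi_family(l)]] %||% 0,
                     numeric(1))
    # voxel x class amplitudes (mixed = mean of the three class patterns)
    pat_mixed <- rowMeans(patterns)
    gain_same <- 1 - effects$adaptation_gain
    amp <- cbind(
      small = gain_same * effects$common_effect + subj_scale * pe_vox * patterns[, "small"],
      large = gain_same * effects$common_effect + subj_scale * pe_vox * patterns[, "large"],
      mixed = effects$common_effect + subj_scale * pe_vox * pat_mixed)
    runs <- vector("list", length(design$runs))
    reg_list <- vector("list", length(design$runs))
    for (rr in seq_along(design$runs)) {
      run <- design$runs[[rr]]
      R <- convolved_regressors(run, run$blocks$size)
      R <- R[, c("small", "large", "mixed"), drop = FALSE]
      reg_list[[rr]] <- R
      nv <- run$n_volumes
      signal <- amp %*% t(R)
      rseed <- derive_seed(seed, 7L, rr)
      noise_mat <- with_seed(rseed, {
        ntot <- nvx + n_background
        e <- matrix(rnorm(ntot * nv, 0, noise$sd * sqrt(1 - noise$ar_rho^2)),
                    ntot, nv)
        if (noise$ar_rho != 0) {
          e[, 1] <- e[, 1] / sqrt(1 - noise$ar_rho^2)
          for (tpt in 2:nv) e[, tpt] <- noise$ar_rho * e[, tpt - 1] + e[, tpt]
        }
        base <- rnorm(1, 0, noise$baseline_sd)
        drift <- rnorm(1, 0, noise$drift_sd)
        tline <- (seq_len(nv) - 1) / max(1, nv - 1) - 0.5
        sweep(e, 2, base + drift * tline, "+")
      })
      Y <- noise_mat
      Y[seq_len(nvx), ] <- Y[seq_len(nvx), ] + signal
      Y <- Y + 100
      rownames(Y) <- c(as.character(vox),
                       if (n_background > 0) paste0("bg", seq_len(n_background)))
      runs[[rr]] <- Y
    }
    structure(list(runs = runs,
                   truth = list(patterns = patterns, amplitudes = amp,
                                informative_voxels = vox[sort(unique(informative))],
                                subject_scale = subj_scale,
                                regressors = reg_list,
                                effects = effects, noise = noise, seed = seed),
                   atlas = atlas, design = design),
              class = "bold_subject")
  })
}
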