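#' Full pipeline configuration
#'
#' Nested configuration for the end-to-end synthetic experiment:
#' design -> eye traces -> QC -> BOLD -> GLM -> MVPA -> group inference.
#'
#' @param n_subjects default 17.
#' @param runs_per_subject_schedule integer vector recycled over subjects
#'   (e.g. `c(rep(5, 13), rep(6, 4))` reproduces the 13x5 + 4x6 split);
#'   default uniform `design$runs_per_subject`.
#' @param design,oculo,effects,noise,glm,mvpa,inference,rules nested module
#'   configurations (see the respective constructors).
#' @param atlas_sizes named ROI voxel counts (default [default_roi_sizes()]).
#' @param grid a [grid_spec()].
#' @param do_eye_qc simulate eye traces and apply QC exclusions (default
#'   TRUE).
#' @param do_univariate run the per-condition GLM branch and group voxel
#'   contrasts (default FALSE; slower).
#' @param do_feature_curve compute accuracy-vs-feature-count curves
#'   (default FALSE; slower).
#' @param bad_block_rates optional list(drop, blink, wrong_hemifield) of
#'   per-block injection rates for QC exercise (default all 0).
#' @param seed master seed.
#' @param out_dir optional artifact directory (TSV tables are written there).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 17L,
                            runs_per_subject_schedule = NULL,
                            design = design_params(),
                            oculo = oculo_params(),
                            effects = effect_spec(),
                            noise = noise_config(),
                            glm = glm_config(),
                            mvpa = mvpa_config(),
                            inference = inference_config(),
                            rules = saccade_rules(),
                            atlas_sizes = default_roi_sizes(),
                            grid = grid_spec(),
                            do_eye_qc = TRUE,
                            do_univariate = FALSE,
                            do_feature_curve = FALSE,
                            bad_block_rates = list(drop = 0, blink = 0, wrong_hemifield = 0),
                            seed = 1L,
                            out_dir = NULL) {
  if (n_subjects < 2) stopf("invalid parameter: n_subjects >= 2 required")
  sched <- runs_per_subject_schedule %||% rep(design$runs_per_subject, n_subjects)
  sched <- rep_len(as.integer(sched), n_subjects)
  structure(list(n_subjects = as.integer(n_subjects),
                 runs_schedule = sched, design = design, oculo = oculo,
                 effects = effects, noise = noise, glm = glm, mvpa = mvpa,
                 inference = inference, rules = rules,
                 atlas_sizes = atlas_sizes, grid = grid,
                 do_eye_qc = isTRUE(do_eye_qc),
                 do_univariate = isTRUE(do_univariate),
                 do_feature_curve = isTRUE(do_feature_curve),
                 bad_block_rates = bad_block_rates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# per-block beta-series GLM for one run; returns block betas, the per-run
# localizer (mean block beta = all saccades > rest), and condition betas
fit_run_glms <- function(Y, run, config, do_univariate = FALSE) {
  Yt <- t(Y)  # time x voxel
  Yf <- gaussian_highpass(Yt, config$glm$highpass_sigma_s, run$tr_s)
  Xb <- build_design_matrix(run, glm_config(mode = "per_block",
                                            highpass_sigma_s = config$glm$highpass_sigma_s,
                                            temporal_derivatives = config$glm$temporal_derivatives,
                                            n_motion = config$glm$n_motion))
  fit <- fit_glm(Yf, Xb)
  block_rows <- grep("^block_", rownames(fit$betas))
  block_betas <- fit$betas[block_rows, , drop = FALSE]
  out <- list(block_betas = block_betas,
              localizer = colMeans(block_betas))
  if (do_univariate) {
    Xc <- build_design_matrix(run, glm_config(mode = "per_condition",
                                              highpass_sigma_s = config$glm$highpass_sigma_s,
                                              temporal_derivatives = config$glm$temporal_derivatives,
                                              n_motion = config$glm$n_motion))
    fitc <- fit_glm(Yf, Xc)
    cond_rows <- match(unique(run$blocks$condition), rownames(fitc$betas))
    out$cond_betas <- fitc$betas[cond_rows, , drop = FALSE]
  }
  out
}

#' Run the full synthetic decoding pipeline
#'
#' Executes, per subject: design generation, optional eye-trace simulation
#' and QC, BOLD simulation with the configured ground truth, high-pass
#' filtering, per-block GLM, and ROI-wise leave-one-run-out SVM decoding
#' (QC-invalid blocks are excluded from the sample sets). Group stage:
#' sign-flip max-t permutation test over the ROI family, optional
#' accuracy-vs-size curves, optional univariate large-vs-small and
#' adaptation contrasts with within-ROI max-t correction, and paired
#' behavioral tests (endpoint variability and peak velocity, large vs
#' small). Fully deterministic given the master seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`; see the elements written by the
#'   function (`accuracy`, `group`, `exclusions`, `behavioral`,
#'   `feature_curves`, `contrasts`, `config`, `timings`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, t0) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  t0 <- proc.time()[["elapsed"]]
  atlas <- build_atlas(config$grid, config$atlas_sizes,
                       seed = derive_seed(config$seed, 11L))
  tick("atlas", t0)

  roi_labels <- names(atlas$masks)
  n_sub <- config$n_subjects
  acc_rows <- list()
  curve_rows <- list()
  qc_rows <- list()
  behav_rows <- list()
  contrast_maps <- list(large_vs_small = list(), adaptation = list())
  subj_ids <- sprintf("sub-%02d", seq_len(n_sub))

  t0 <- proc.time()[["elapsed"]]
  for (s in seq_len(n_sub)) {
    sseed <- derive_seed(config$seed, 1000L, s)
    design <- make_experiment_design(config$design, subject_id = subj_ids[s],
                                     seed = sseed, runs = config$runs_schedule[s])
    # eye branch: traces, detection, per-block validity
    valid_by_run <- lapply(design$runs, function(r) rep(TRUE, nrow(r$blocks)))
    if (config$do_eye_qc) {
      for (rr in seq_along(design$runs)) {
        run <- design$runs[[rr]]
        bad <- inject_bad_blocks(run,
                                 drop_rate = config$bad_block_rates$drop %||% 0,
                                 blink_rate = config$bad_block_rates$blink %||% 0,
                                 wrong_hemifield_rate = config$bad_block_rates$wrong_hemifield %||% 0,
                                 seed = derive_seed(sseed, 21L, rr))
        trace <- simulate_trace(run, config$oculo, seed = derive_seed(sseed, 22L, rr),
                                bad_blocks = bad, run_id = rr,
                                subject_id = subj_ids[s])
        qc <- qc_run(trace, run, config$rules)
        qc$subject <- subj_ids[s]
        qc$run <- rr
        qc_rows[[length(qc_rows) + 1L]] <- qc
        valid_by_run[[rr]] <- qc$valid
        # behavioral summaries from valid small/large blocks
        for (sz in c("small", "large")) {
          sel <- qc$valid & qc$size == sz
          if (any(sel)) {
            ev <- attr(qc, "events")
            behav_rows[[length(behav_rows) + 1L]] <- data.frame(
              subject = subj_ids[s], run = rr, size = sz,
              endpoint_var = mean(qc$sd_amplitude_deg[sel]^2, na.rm = TRUE),
              peak_velocity = mean(qc$mean_peak_velocity[sel], na.rm = TRUE),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    bold <- simulate_subject(design, atlas, config$effects, config$noise,
                             seed = derive_seed(sseed, 23L))
    betas_by_run <- vector("list", length(design$runs))
    cond_by_run <- vector("list", length(design$runs))
    localizer <- matrix(NA_real_, length(atlas$voxels), length(design$runs))
    for (rr in seq_along(design$runs)) {
      g <- fit_run_glms(bold$runs[[rr]], design$runs[[rr]], config,
                        do_univariate = config$do_univariate)
      betas_by_run[[rr]] <- g$block_betas
      localizer[, rr] <- g$localizer
      if (config$do_univariate) cond_by_run[[rr]] <- g$cond_betas
    }
    if (config$do_univariate) {
      cond_mean <- Reduce(`+`, cond_by_run) / length(cond_by_run)
      contrast_maps$large_vs_small[[s]] <-
        compute_contrast(cond_mean, contrast_weights("large_vs_small"))
      contrast_maps$adaptation[[s]] <-
        compute_contrast(cond_mean, contrast_weights("adaptation"))
    }
    # per-ROI decoding (drop QC-invalid blocks from the sample sets)
    vox_names <- rownames(bold$runs[[1]])
    for (roi in roi_labels) {
      mask <- atlas$masks[[roi]]
      cols <- match(as.character(mask$voxels), vox_names)
      b_roi <- lapply(seq_along(betas_by_run), function(rr) {
        keep <- valid_by_run[[rr]]
        betas_by_run[[rr]][keep, cols, drop = FALSE]
      })
      sizes <- lapply(seq_along(design$runs), function(rr)
        design$runs[[rr]]$blocks$size[valid_by_run[[rr]]])
      sset <- make_sample_set(b_roi, sizes, subject_id = subj_ids[s])
      loc_roi <- localizer[match(mask$voxels, atlas$voxels), , drop = FALSE]
      acc <- loro_accuracy(sset, config$mvpa)
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        subject = subj_ids[s], roi = roi, n_features = mask$size,
        accuracy_pct = as.numeric(acc), stringsAsFactors = FALSE)
      if (config$do_feature_curve) {
        cv <- accuracy_vs_size(sset, loc_roi, config$mvpa)
        cv$subject <- subj_ids[s]
        cv$roi <- roi
        curve_rows[[length(curve_rows) + 1L]] <- cv
      }
    }
  }
  tick("subjects", t0)

  accuracy <- do.call(rbind, acc_rows)
  acc_mat <- matrix(accuracy$accuracy_pct, nrow = n_sub, byrow = TRUE,
                    dimnames = list(subj_ids, roi_labels))

  # eye-based exclusions
  exclusions <- NULL
  retained_subjects <- subj_ids
  if (config$do_eye_qc && length(qc_rows)) {
    qc_all <- do.call(rbind, qc_rows)
    exclusions <- apply_exclusions(qc_all)
    retained_subjects <- setdiff(subj_ids, exclusions$excluded_subjects)
    if (length(retained_subjects) < 2) {
      warning("fewer than 2 subjects survive exclusion; group statistics use all subjects")
      retained_subjects <- subj_ids
    }
  }
  t0 <- proc.time()[["elapsed"]]
  group <- signflip_maxt(acc_mat[retained_subjects, , drop = FALSE],
                         config$inference, method = "montecarlo")
  tick("inference", t0)

  # feature-curve group tests, one permutation family per set size
  feature_curves <- NULL
  if (config$do_feature_curve && length(curve_rows)) {
    fc <- do.call(rbind, curve_rows)
    group_by_k <- lapply(split(fc, fc$n_features), function(d) {
      m <- tapply(d$accuracy_pct, list(d$subject, d$roi), mean)
      m <- m[retained_subjects[retained_subjects %in% rownames(m)], , drop = FALSE]
      ok <- colSums(!is.na(m)) == nrow(m)
      signflip_maxt(m[, ok, drop = FALSE], config$inference, method = "montecarlo")
    })
    feature_curves <- list(table = fc, group = group_by_k)
  }

  # univariate branch: group contrasts within each ROI
  contrasts <- NULL
  if (config$do_univariate) {
    contrasts <- list()
    for (nm in names(contrast_maps)) {
      maps <- do.call(rbind, contrast_maps[[nm]])
      rownames(maps) <- subj_ids
      maps <- maps[retained_subjects, , drop = FALSE]
      per_roi <- lapply(atlas$masks, function(mask) {
        cols <- match(as.character(mask$voxels), colnames(maps) %||%
                        as.character(atlas$voxels))
        group_voxel_contrast(maps[, match(mask$voxels, atlas$voxels), drop = FALSE],
                             mask, config$inference)
      })
      contrasts[[nm]] <- per_roi
    }
  }

  # behavioral paired tests on per-subject summaries
  behavioral <- NULL
  if (length(behav_rows)) {
    bh <- do.call(rbind, behav_rows)
    bh <- bh[bh$subject %in% retained_subjects, ]
    agg <- aggregate(cbind(endpoint_var, peak_velocity) ~ subject + size, bh, mean)
    wide_var <- tapply(agg$endpoint_var, list(agg$subject, agg$size), mean)
    wide_vel <- tapply(agg$peak_velocity, list(agg$subject, agg$size), mean)
    behavioral <- list(
      endpoint_variability = paired_t(wide_var[, "large"], wide_var[, "small"]),
      peak_velocity = paired_t(wide_vel[, "large"], wide_vel[, "small"]),
      summary = agg)
  }

  report <- structure(list(
    accuracy = accuracy,
    accuracy_matrix = acc_mat,
    group = group,
    exclusions = exclusions,
    retained_subjects = retained_subjects,
    behavioral = behavioral,
    feature_curves = feature_curves,
    contrasts = contrasts,
    atlas = atlas,
    config = config,
    version = as.character(utils::packageVersion("saccdecode")),
    timings = c(timings, total = round(proc.time()[["elapsed"]] - t_start, 2))),
    class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write report tables to an artifact directory
#'
#' @param report a `run_report`.
#' @param out_dir directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$accuracy, "accuracy.tsv")
  wt(report$group$table, "group_inference.tsv")
  if (!is.null(report$exclusions)) {
    wt(report$exclusions$excluded_blocks, "excluded_blocks.tsv")
    wt(report$exclusions$run_invalid_fraction, "run_invalid_fraction.tsv")
  }
  if (!is.null(report$feature_curves)) wt(report$feature_curves$table, "feature_curves.tsv")
  write_atlas_tsv(report$atlas, file.path(out_dir, "atlas.tsv"))
  paths <- c(paths, file.path(out_dir, "atlas.tsv"))
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat("saccdecode run report (version ", x$version, ")\n", sep = "")
  cat("subjects:", x$config$n_subjects,
      "| retained:", length(x$retained_subjects), "\n")
  means <- colMeans(x$accuracy_matrix[x$retained_subjects, , drop = FALSE])
  tab <- x$group$table
  cat(sprintf("%-8s %8s %8s %10s %5s\n", "roi", "mean_acc", "t", "p_fwe", "sig"))
  for (r in seq_len(nrow(tab)))
    cat(sprintf("%-8s %8.1f %8.2f %10.4g %5s\n", tab$roi[r], means[tab$roi[r]],
                tab$t_obs[r], tab$p_fwe[r], ifelse(tab$significant[r], "*", "")))
  cat("max-t critical value:", round(x$group$critical_t, 3), "\n")
  if (!is.null(x$behavioral)) {
    cat(sprintf("behavior: endpoint var t(%d)=%.2f; peak velocity t(%d)=%.2f (large vs small)\n",
                x$behavioral$endpoint_variability$df,
                x$behavioral$endpoint_variability$statistic,
                x$behavioral$peak_velocity$df,
                x$behavioral$peak_velocity$statistic))
  }
  invisible(x)
}

#' Figures: per-ROI accuracy bars and feature-count curves
#'
#' Produces the two standard report figures as PDF files: a bar chart of
#' group mean accuracy per ROI with the 50% chance line and significance
#' markers, and (when feature curves were computed) one accuracy curve per
#' ROI over its feature-count grid with the permutation-derived
#' significance level. Skips the curve figure with a message when no
#' feature-count analysis is present.
#'
#' @param report a `run_report`.
#' @param out_dir output directory.
#' @return character vector of created file paths.
#' @export
make_figures <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  means <- colMeans(report$accuracy_matrix[report$retained_subjects, , drop = FALSE])
  tab <- report$group$table
  p1 <- file.path(out_dir, "accuracy_by_roi.pdf")
  grDevices::pdf(p1, width = 7, height = 4.5)
  bp <- graphics::barplot(means, ylim = c(0, max(75, means + 8)),
                          ylab = "decoding accuracy (%)", las = 2,
                          col = ifelse(tab$significant[match(names(means), tab$roi)],
                                       "firebrick", "grey70"))
  graphics::abline(h = 50, lty = 2)
  sig <- tab$significant[match(names(means), tab$roi)]
  if (any(sig)) graphics::text(bp[sig], means[sig] + 3, "*", cex = 1.4)
  grDevices::dev.off()
  paths <- c(paths, p1)
  if (!is.null(report$feature_curves)) {
    fc <- report$feature_curves$table
    agg <- aggregate(accuracy_pct ~ roi + n_features, fc, mean)
    p2 <- file.path(out_dir, "accuracy_vs_size.pdf")
    grDevices::pdf(p2, width = 7, height = 4.5)
    rois <- unique(agg$roi)
    cols <- grDevices::rainbow(length(rois))
    graphics::plot(range(agg$n_features), range(c(45, agg$accuracy_pct)),
                   type = "n", xlab = "number of voxels",
                   ylab = "decoding accuracy (%)")
    for (i in seq_along(rois)) {
      d <- agg[agg$roi == rois[i], ]
      graphics::lines(d$n_features, d$accuracy_pct, col = cols[i], lwd = 2)
    }
    graphics::abline(h = 50, lty = 2)
    graphics::legend("topleft", legend = rois, col = cols, lwd = 2, cex = 0.6)
    grDevices::dev.off()
    paths <- c(paths, p2)
  } else {
    message("no feature-count analysis present; curve figure skipped")
  }
  paths
}
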