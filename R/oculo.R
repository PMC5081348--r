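#' Oculomotor simulation parameters
#'
#' Kinematic and noise parameters for the 60 Hz monocular horizontal
#' eye-trace simulator. Peak velocity follows the main-sequence law
#' `V(A) = vmax * (1 - exp(-A / a0))`; endpoint scatter grows linearly with
#' amplitude, which is what makes large saccades more variable than small
#' ones.
#'
#' @param sampling_hz trace sampling rate (default 60).
#' @param latency_mean_s,latency_sd_s saccadic reaction time distribution
#'   (Gaussian, truncated at `latency_min_s`); defaults 0.18 and 0.03 s.
#' @param latency_min_s lower truncation, default 0.08 s (instructed
#'   non-anticipatory responding).
#' @param vmax_deg_s main-sequence velocity asymptote (default 500 deg/s).
#' @param a0_deg main-sequence amplitude constant (default 14 deg).
#' @param endpoint_sd_slope endpoint SD as a fraction of saccade amplitude
#'   (default 0.05).
#' @param endpoint_trunc_sd endpoint error truncation in SD units (default
#'   2): overshoots beyond this would in reality be cleaned up by corrective
#'   saccades, which are not modelled; truncation also guarantees that every
#'   executed saccade's amplitude stays inside its nominal QC class.
#' @param noise_sd_deg fixation position noise SD (default 0.15 deg).
#' @param drift_tau_s time constant of the post-saccadic corrective glissade
#'   (default 0.1 s): after landing, gaze glides exponentially from the
#'   endpoint onto the visible target box. Without this correction the
#'   landing errors of large saccades (SD up to 1.5 deg) compound across
#'   the centrifugal/centripetal sequence and detected amplitudes leave
#'   their nominal class; a smooth glide corrects them without producing a
#'   separately detectable saccade. Larger landing errors still leave a
#'   proportionally larger footprint in the detected fixation positions
#'   (detection stabilizes before the glide completes), preserving the
#'   amplitude-dependent variability effect.
#' @param refractory_s minimum intersaccadic interval (default 0.2 s):
#'   a new saccade cannot launch until this long after the previous one
#'   lands. Besides being physiological, it guarantees the detector a
#'   stable fixation window between any two saccades, so clean traces are
#'   always fully QC-valid.
#' @param blink_rate_hz spontaneous blink rate; default 0 (off).
#' @param seed default seed.
#' @return list of class `oculo_params`.
#' @export
oculo_params <- function(sampling_hz = 60,
                         latency_mean_s = 0.18, latency_sd_s = 0.03,
                         latency_min_s = 0.08,
                         vmax_deg_s = 500, a0_deg = 14,
                         endpoint_sd_slope = 0.05,
                         endpoint_trunc_sd = 2,
                         noise_sd_deg = 0.15,
                         drift_tau_s = 0.1,
                         refractory_s = 0.2,
                         blink_rate_hz = 0,
                         seed = 1L) {
  assert_scalar_num(sampling_hz, "sampling_hz", lower = 1e-9)
  assert_scalar_num(vmax_deg_s, "vmax_deg_s", lower = 1e-9)
  assert_scalar_num(a0_deg, "a0_deg", lower = 1e-9)
  for (nm in c("latency_sd_s", "endpoint_sd_slope", "noise_sd_deg", "blink_rate_hz"))
    assert_scalar_num(get(nm), nm, lower = 0)
  structure(as.list(environment()), class = "oculo_params")
}

#' Main-sequence peak velocity
#'
#' `V(A) = vmax * (1 - exp(-A / a0))`: strictly increasing in amplitude,
#' zero at zero, saturating at `vmax`.
#'
#' @param amplitude_deg saccade amplitude(s), degrees, `>= 0`.
#' @param params an [oculo_params()] object.
#' @return peak velocity in deg/s (vectorized).
#' @export
peak_velocity <- function(amplitude_deg, params = oculo_params()) {
  if (any(amplitude_deg < 0)) stopf("invalid parameter: negative amplitude")
  params$vmax_deg_s * (1 - exp(-amplitude_deg / params$a0_deg))
}

#' Sample per-block bad-behavior injections for QC testing
#'
#' Marks blocks of a run design as `drop` (no saccades made), `blink` (eyes
#' closed, missing samples), or `wrong_hemifield` (saccades mirrored), each
#' with an independent per-block rate. A block receives at most one mode.
#'
#' @param run a `run_design`.
#' @param drop_rate,blink_rate,wrong_hemifield_rate per-block probabilities.
#' @param seed integer seed.
#' @return data.frame with columns `block`, `mode` (possibly zero rows).
#' @export
inject_bad_blocks <- function(run, drop_rate = 0, blink_rate = 0,
                              wrong_hemifield_rate = 0, seed = 1L) {
  nb <- nrow(run$blocks)
  with_seed(seed, {
    u <- runif(nb)
    p1 <- drop_rate; p2 <- p1 + blink_rate; p3 <- p2 + wrong_hemifield_rate
    mode <- rep(NA_character_, nb)
    mode[u < p1] <- "drop"
    mode[u >= p1 & u < p2] <- "blink"
    mode[u >= p2 & u < p3] <- "wrong_hemifield"
    data.frame(block = which(!is.na(mode)), mode = mode[!is.na(mode)],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a 60 Hz horizontal eye trace for one run
#'
#' Gaze executes the run's target schedule: after a truncated-Gaussian
#' latency the eye moves to the target plus Gaussian endpoint error
#' (SD = `endpoint_sd_slope * amplitude`) along a raised-cosine position
#' profile whose duration is set so peak velocity obeys the main-sequence
#' law ([peak_velocity()]); between saccades gaze holds position with white
#' fixation noise. Saccades that would start before the previous one
#' finished are queued. Deterministic given the seed.
#'
#' @param run a `run_design`.
#' @param params an [oculo_params()] object.
#' @param seed integer seed.
#' @param bad_blocks optional data.frame from [inject_bad_blocks()].
#' @param run_id,subject_id identifiers stored on the trace.
#' @return list of class `eye_trace`: `time_s`, `gaze_x_deg` (NA during
#'   blinks), `sampling_hz`, `run_id`, `subject_id`, and a `truth` element
#'   listing every executed saccade (start time, start/end position,
#'   amplitude, peak velocity) plus the injected bad blocks.
#' @export
simulate_trace <- function(run, params = oculo_params(), seed = params$seed,
                           bad_blocks = NULL, run_id = 1L, subject_id = "sub-01") {
  fs <- params$sampling_hz
  n <- round(run$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  bad <- bad_blocks %||% data.frame(block = integer(0), mode = character(0))
  with_seed(seed, {
    x <- numeric(n)
    cur_i <- 1L      # next sample index to fill
    free_t <- 0      # time at which the eye is next free to move
    # fixation state: gaze glides from `hold_from` toward `hold_target`
    # with time constant drift_tau_s, starting at hold_t0
    hold_from <- 0; hold_target <- 0; hold_t0 <- 0
    pos_at <- function(t)
      hold_target + (hold_from - hold_target) * exp(-pmax(0, t - hold_t0) / params$drift_tau_s)
    sacc <- list()
    blocks <- run$blocks
    for (b in seq_len(nrow(blocks))) {
      mode <- bad$mode[match(b, bad$block)]
      if (identical(mode, "drop")) next
      times <- blocks$target_times_s[[b]] + blocks$onset_s[b]
      pos <- blocks$target_positions_deg[[b]]
      if (identical(mode, "wrong_hemifield")) pos <- -pos
      for (j in seq_along(times)) {
        lat <- max(params$latency_min_s,
                   rnorm(1, params$latency_mean_s, params$latency_sd_s))
        go_t <- max(times[j] + lat, free_t)
        cur_pos <- pos_at(go_t)
        amp_nominal <- pos[j] - cur_pos
        if (abs(amp_nominal) < 1e-9) next
        esd <- params$endpoint_sd_slope * abs(amp_nominal)
        ez <- max(-params$endpoint_trunc_sd,
                  min(params$endpoint_trunc_sd, rnorm(1)))
        end_pos <- pos[j] + ez * esd
        amp <- end_pos - cur_pos
        vp <- peak_velocity(abs(amp), params)
        dur <- max(abs(amp) * pi / (2 * vp), 1 / fs)
        i0 <- min(n + 1L, floor(go_t * fs) + 1L)
        i1 <- min(n, ceiling((go_t + dur) * fs))
        if (i0 > cur_i) x[cur_i:(i0 - 1L)] <- pos_at(tt[cur_i:(i0 - 1L)])
        if (i1 >= i0) {
          ph <- pmin(pmax((tt[i0:i1] - go_t) / dur, 0), 1)
          x[i0:i1] <- cur_pos + amp * (1 - cos(pi * ph)) / 2
        }
        sacc[[length(sacc) + 1L]] <- data.frame(
          block = b, target_time_s = times[j], start_s = go_t,
          from_deg = cur_pos, to_deg = end_pos, amplitude_deg = abs(amp),
          peak_velocity_deg_s = vp)
        hold_from <- end_pos; hold_target <- pos[j]; hold_t0 <- go_t + dur
        cur_i <- max(cur_i, i1 + 1L)
        free_t <- go_t + dur + params$refractory_s
      }
    }
    if (cur_i <= n) x[cur_i:n] <- pos_at(tt[cur_i:n])
    if (params$noise_sd_deg > 0) x <- x + rnorm(n, 0, params$noise_sd_deg)
    # block-level blinks: samples missing for the whole block window
    blink_blocks <- bad$block[bad$mode == "blink"]
    for (b in blink_blocks) {
      w <- tt >= blocks$onset_s[b] & tt < blocks$onset_s[b] + blocks$duration_s[b] + 0.5
      x[w] <- NA_real_
    }
    truth <- list(
      saccades = if (length(sacc)) do.call(rbind, sacc) else NULL,
      bad_blocks = bad)
    structure(list(time_s = tt, gaze_x_deg = x, sampling_hz = fs,
                   run_id = run_id, subject_id = subject_id, truth = truth),
              class = "eye_trace")
  })
}

#' Write / read eye traces as TSV (`time_s`, `gaze_x_deg`; missing empty)
#'
#' @param trace an `eye_trace`.
#' @param path file path.
#' @return `path` invisibly (write); an `eye_trace` (read).
#' @export
write_trace_tsv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, gaze_x_deg = trace$gaze_x_deg)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  dt <- diff(df$time_s)
  fs <- 1 / median(dt)
  structure(list(time_s = df$time_s, gaze_x_deg = df$gaze_x_deg,
                 sampling_hz = fs, run_id = NA, subject_id = NA,
                 truth = NULL),
            class = "eye_trace")
}
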