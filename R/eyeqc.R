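#' Saccade detection and classification rules
#'
#' A saccade is a horizontal deviation of more than `detect_threshold_deg`
#' from the current fixation position. Amplitudes are classed as small
#' (2-6 deg inclusive), medium (strictly between 6 and 15), or large
#' (> 20); amplitudes in \[15, 20\] fall in the rules' gap and are
#' `unclassified` (any block containing one is invalid).
#'
#' @param detect_threshold_deg detection threshold (default 2).
#' @param small_range_deg inclusive small range, default `c(2, 6)`.
#' @param medium_range_deg open medium range, default `c(6, 15)`.
#' @param large_min_deg exclusive large lower bound, default 20.
#' @param stab_window_s post-saccadic window used both to declare
#'   re-stabilization and to estimate the new fixation position by its
#'   median (default 0.1 s).
#' @param stab_range_deg maximum within-window range counted as stable
#'   (default 1 deg).
#' @return list of class `saccade_rules`.
#' @export
saccade_rules <- function(detect_threshold_deg = 2,
                          small_range_deg = c(2, 6),
                          medium_range_deg = c(6, 15),
                          large_min_deg = 20,
                          stab_window_s = 0.1,
                          stab_range_deg = 1) {
  if (detect_threshold_deg > small_range_deg[1])
    stopf("invalid parameter: detect threshold above small lower bound")
  if (small_range_deg[2] > medium_range_deg[1] || medium_range_deg[2] > large_min_deg)
    stopf("invalid parameter: amplitude class ranges overlap")
  structure(as.list(environment()), class = "saccade_rules")
}

#' Classify saccade amplitudes
#'
#' @param amplitude_deg unsigned amplitudes, each strictly above the
#'   detection threshold.
#' @param rules a [saccade_rules()] object.
#' @return character vector in `{small, medium, large, unclassified}`.
#' @export
classify_amplitude <- function(amplitude_deg, rules = saccade_rules()) {
  if (any(amplitude_deg <= rules$detect_threshold_deg))
    stopf("invalid parameter: amplitude at or below detection threshold (%g deg)",
          rules$detect_threshold_deg)
  out <- rep("unclassified", length(amplitude_deg))
  out[amplitude_deg >= rules$small_range_deg[1] &
      amplitude_deg <= rules$small_range_deg[2]] <- "small"
  out[amplitude_deg > rules$medium_range_deg[1] &
      amplitude_deg < rules$medium_range_deg[2]] <- "medium"
  out[amplitude_deg > rules$large_min_deg] <- "large"
  out
}

#' Detect saccades in an eye trace
#'
#' Stateful scan: the current fixation position is tracked as the median of
#' the trailing stabilization window; when gaze departs more than the
#' detection threshold from it, the scan advances until the trace
#' re-stabilizes (window range below `stab_range_deg`), takes the median of
#' that window as the new fixation, and emits an event with amplitude
#' `|new fixation - old fixation|` if it exceeds the threshold. A crude
#' peak-velocity estimate (max sample-to-sample speed over the event) is
#' attached for behavioral summaries.
#'
#' @param trace an `eye_trace`.
#' @param rules a [saccade_rules()] object.
#' @return data.frame of class `saccade_events` with columns `onset_s`,
#'   `amplitude_deg`, `direction` (`left`/`right`), `class`,
#'   `peak_velocity_deg_s`. Attribute `missing_data` is `TRUE` when the
#'   trace contains missing samples (all-missing traces return zero events).
#' @export
detect_saccades <- function(trace, rules = saccade_rules()) {
  x <- trace$gaze_x_deg
  tt <- trace$time_s
  fs <- trace$sampling_hz
  n <- length(x)
  fw <- max(2L, round(rules$stab_window_s * fs))
  empty <- data.frame(onset_s = numeric(0), amplitude_deg = numeric(0),
                      direction = character(0), class = character(0),
                      peak_velocity_deg_s = numeric(0))
  has_na <- anyNA(x)
  if (all(is.na(x))) {
    attr(empty, "missing_data") <- TRUE
    class(empty) <- c("saccade_events", class(empty))
    return(empty)
  }
  events <- vector("list", 64L)
  ne <- 0L
  first_ok <- which(!is.na(x))[1]
  fix_pos <- median(x[first_ok:min(n, first_ok + fw - 1L)], na.rm = TRUE)
  i <- first_ok
  while (i <= n) {
    xi <- x[i]
    if (is.na(xi)) { i <- i + 1L; next }
    if (abs(xi - fix_pos) > rules$detect_threshold_deg) {
      onset_i <- i
      j <- i
      repeat {
        if (j + fw - 1L > n) { j <- n - fw + 1L; break }
        w <- x[j:(j + fw - 1L)]
        if (anyNA(w)) { j <- j + 1L; next }
        if (max(w) - min(w) < rules$stab_range_deg) break
        j <- j + 1L
      }
      w <- x[j:min(n, j + fw - 1L)]
      new_fix <- median(w, na.rm = TRUE)
      amp <- abs(new_fix - fix_pos)
      if (amp > rules$detect_threshold_deg) {
        seg <- x[onset_i:min(n, j + 1L)]
        pv <- if (length(seg) > 1) max(abs(diff(seg)), na.rm = TRUE) * fs else NA_real_
        ne <- ne + 1L
        if (ne > length(events)) events <- c(events, vector("list", length(events)))
        events[[ne]] <- data.frame(
          onset_s = tt[onset_i], amplitude_deg = amp,
          direction = if (new_fix > fix_pos) "right" else "left",
          class = classify_amplitude(amp, rules),
          peak_velocity_deg_s = pv)
      }
      fix_pos <- new_fix
      i <- j + fw
    } else {
      lo <- max(1L, i - fw + 1L)
      fix_pos <- median(x[lo:i], na.rm = TRUE)
      i <- i + 1L
    }
  }
  out <- if (ne > 0) do.call(rbind, events[seq_len(ne)]) else empty
  attr(out, "missing_data") <- has_na
  class(out) <- c("saccade_events", class(out))
  out
}

#' Validate one block's detected saccades against its schedule
#'
#' A block is valid iff exactly `saccades_per_block` events fall in its
#' window, their amplitude classes match the scheduled eccentricities
#' (outward and return saccades alike), and their directions match the
#' block's hemifield for outward saccades and the opposite for returns.
#' Reason precedence: `missing_data`, `count_mismatch`, `class_mismatch`,
#' `direction_mismatch`.
#'
#' @param events a `saccade_events` data.frame (whole-run detection output).
#' @param block one row of a `run_design` blocks data.frame.
#' @param rules a [saccade_rules()] object.
#' @param missing logical: block window contained missing samples.
#' @param window_pad_s extra time after block offset in which the final
#'   return saccade may land (latency allowance; default 0.6 s).
#' @return list of class `block_qc`: `block`, `valid`, `reason`, `events`.
#' @export
validate_block <- function(events, block, rules = saccade_rules(),
                           missing = FALSE, window_pad_s = 0.6) {
  t0 <- block$onset_s
  t1 <- block$onset_s + block$duration_s + window_pad_s
  ev <- events[events$onset_s >= t0 & events$onset_s < t1, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  n_expect <- length(block$target_positions_deg[[1]])
  result <- function(valid, reason)
    structure(list(block = block$index, valid = valid, reason = reason,
                   events = ev), class = "block_qc")
  if (missing) return(result(FALSE, "missing_data"))
  if (nrow(ev) != n_expect) return(result(FALSE, "count_mismatch"))
  pos <- block$target_positions_deg[[1]]
  ecc <- abs(pos[pos != 0])                      # outward eccentricities, in order
  exp_class <- classify_amplitude(ecc, rules)
  exp_class <- rep(exp_class, each = 2)          # out + return share the class
  out_dir <- if (block$hemifield == "left") "left" else "right"
  ret_dir <- if (out_dir == "left") "right" else "left"
  exp_dir <- rep(c(out_dir, ret_dir), length.out = n_expect)
  if (!all(ev$class == exp_class)) return(result(FALSE, "class_mismatch"))
  if (!all(ev$direction == exp_dir)) return(result(FALSE, "direction_mismatch"))
  result(TRUE, "ok")
}

#' QC one run: detect saccades and validate every block
#'
#' @param trace an `eye_trace` for the run.
#' @param run the matching `run_design`.
#' @param rules a [saccade_rules()] object.
#' @return data.frame with one row per block: `block`, `valid`, `reason`,
#'   plus per-block mean detected amplitude/velocity summaries used by the
#'   behavioral analyses. The detection output is attached as attribute
#'   `events`.
#' @export
qc_run <- function(trace, run, rules = saccade_rules()) {
  events <- detect_saccades(trace, rules)
  x <- trace$gaze_x_deg
  tt <- trace$time_s
  rows <- lapply(seq_len(nrow(run$blocks)), function(b) {
    blk <- run$blocks[b, ]
    w <- tt >= blk$onset_s & tt < blk$onset_s + blk$duration_s + 0.6
    miss <- anyNA(x[w])
    qc <- validate_block(events, blk, rules, missing = miss)
    ev <- qc$events
    data.frame(block = blk$index, size = blk$size, hemifield = blk$hemifield,
               valid = qc$valid, reason = qc$reason,
               n_events = nrow(ev),
               mean_amplitude_deg = if (nrow(ev)) mean(ev$amplitude_deg) else NA_real_,
               sd_amplitude_deg = if (nrow(ev) > 1) sd(ev$amplitude_deg) else NA_real_,
               mean_peak_velocity = if (nrow(ev)) mean(ev$peak_velocity_deg_s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "events") <- events
  out
}

#' Apply block, run, and subject exclusion rules to a QC table
#'
#' Invalid blocks are dropped. A run is excluded when more than half of its
#' blocks are invalid; a subject is excluded when more than half of all
#' their blocks (across runs) are invalid. Run exclusion generalizes the
#' single anecdotal 30/36 case into a >50% rule.
#'
#' @param qc data.frame with columns `subject`, `run`, `block`, `valid`
#'   (and optionally `reason`).
#' @return list of class `exclusion_report`: `retained` (valid blocks of
#'   retained runs/subjects), `excluded_subjects`, `excluded_runs`
#'   (data.frame subject/run), `excluded_blocks`, and per-level fractions.
#' @export
apply_exclusions <- function(qc) {
  stopifnot(all(c("subject", "run", "block", "valid") %in% names(qc)))
  subj_frac <- aggregate(valid ~ subject, qc, function(v) mean(!v))
  names(subj_frac)[2] <- "frac_invalid"
  excluded_subjects <- subj_frac$subject[subj_frac$frac_invalid > 0.5]
  run_frac <- aggregate(valid ~ subject + run, qc, function(v) mean(!v))
  names(run_frac)[3] <- "frac_invalid"
  excluded_runs <- run_frac[run_frac$frac_invalid > 0.5 &
                            !(run_frac$subject %in% excluded_subjects),
                            c("subject", "run")]
  keep <- qc$valid &
    !(qc$subject %in% excluded_subjects) &
    !paste(qc$subject, qc$run) %in% paste(excluded_runs$subject, excluded_runs$run)
  excluded_blocks <- qc[!qc$valid, , drop = FALSE]
  structure(list(retained = qc[keep, , drop = FALSE],
                 excluded_subjects = excluded_subjects,
                 excluded_runs = excluded_runs,
                 excluded_blocks = excluded_blocks,
                 subject_invalid_fraction = subj_frac,
                 run_invalid_fraction = run_frac),
            class = "exclusion_report")
}

#' Write a QC report table as TSV
#'
#' @param qc data.frame (subject, run, block, valid, reason, ...).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(qc, path) {
  write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
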