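#' Experimental design parameters
#'
#' Parameters for the saccade block design: six conditions (small, large, or
#' mixed saccade amplitude, in the left or right hemifield), arranged in
#' 4-second mini-blocks of six saccades, separated by jittered central
#' fixation. Defaults reproduce the standard run layout: 36 blocks per run
#' (6 conditions x 6 repeats), 6-8 s fixation gaps, 8 s of lead-in and
#' lead-out fixation, targets at 0/±5/±10/±30 degrees, five runs per subject.
#'
#' @param repeats_per_condition blocks per condition per run (default 6).
#' @param block_duration_s mini-block duration in seconds (default 4).
#' @param saccades_per_block targets per block (default 6; three
#'   centrifugal/centripetal pairs).
#' @param fixation_jitter_s length-2 numeric, uniform inter-block fixation
#'   interval in seconds (default `c(6, 8)`).
#' @param lead_trail_fixation_s fixation at run start and end (default 8).
#' @param target_eccentricities_deg placeholder positions for the
#'   small/medium/large target boxes (default `c(5, 10, 30)`).
#' @param nominal_amplitudes_deg nominal amplitude class values
#'   (default `c(small = 4, medium = 10, large = 30)`); informational only --
#'   amplitude classing is done by the QC rules.
#' @param runs_per_subject default 5.
#' @param tr_s repetition time in seconds, used to compute run volume counts.
#' @param seed default seed used when none is passed to the generators.
#' @return A list of class `design_params`.
#' @export
design_params <- function(repeats_per_condition = 6,
                          block_duration_s = 4,
                          saccades_per_block = 6,
                          fixation_jitter_s = c(6, 8),
                          lead_trail_fixation_s = 8,
                          target_eccentricities_deg = c(small = 5, medium = 10, large = 30),
                          nominal_amplitudes_deg = c(small = 4, medium = 10, large = 30),
                          runs_per_subject = 5,
                          tr_s = 2,
                          seed = 1L) {
  if (repeats_per_condition < 1) stopf("invalid parameter: repeats_per_condition < 1")
  assert_scalar_num(block_duration_s, "block_duration_s", lower = 1e-9)
  if (length(fixation_jitter_s) != 2 || fixation_jitter_s[1] > fixation_jitter_s[2])
    stopf("invalid parameter: fixation_jitter_s must be an interval low <= high")
  if (saccades_per_block %% 2 != 0)
    stopf("invalid parameter: saccades_per_block must be even (out-and-back pairs)")
  sizes <- c("small", "large", "mixed")
  hemis <- c("left", "right")
  conditions <- expand.grid(size = sizes, hemifield = hemis,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions$label <- paste(conditions$size, conditions$hemifield, sep = "_")
  structure(list(
    conditions = conditions,
    repeats_per_condition = as.integer(repeats_per_condition),
    block_duration_s = block_duration_s,
    saccades_per_block = as.integer(saccades_per_block),
    fixation_jitter_s = as.numeric(fixation_jitter_s),
    lead_trail_fixation_s = lead_trail_fixation_s,
    target_eccentricities_deg = target_eccentricities_deg,
    nominal_amplitudes_deg = nominal_amplitudes_deg,
    runs_per_subject = as.integer(runs_per_subject),
    tr_s = tr_s,
    seed = as.integer(seed)
  ), class = "design_params")
}

#' Balanced block sequence via an Eulerian path
#'
#' Orders `k x r` blocks (k conditions, r repeats) so that counts of ordered
#' condition transitions are as uniform as possible. A true m-sequence does
#' not exist for 6 conditions x 6 repeats (perfect pair balance would need 37
#' blocks), so the sequence is built as an Eulerian path on the condition
#' transition multigraph: every ordered pair of distinct conditions receives
#' `q = floor((kr-1)/(k(k-1)))` edges, and the `m = (kr-1) mod k(k-1)`
#' remaining edges walk a random cyclic permutation of the conditions
#' (`m + 1` is always divisible by `k`, since
#' `m + 1 = kr - q k(k-1) = k (r - q(k-1))`, so every condition appears
#' exactly `r` times). Hierholzer's algorithm with seeded random edge choice
#' yields the path. For the default design this guarantees a cross-condition
#' transition-count spread of at most 1.
#'
#' @param params a [design_params()] object.
#' @param seed integer seed; defaults to `params$seed`.
#' @return Character vector of `k * r` condition labels.
#' @export
make_block_sequence <- function(params = design_params(), seed = params$seed) {
  labs <- params$conditions$label
  k <- length(labs)
  r <- params$repeats_per_condition
  if (r < 1) stopf("invalid parameter: repeats_per_condition < 1")
  if (k < 2) return(rep(labs, r))
  n_edges <- k * r - 1
  q <- n_edges %/% (k * (k - 1))
  m <- n_edges %% (k * (k - 1))
  with_seed(seed, {
    counts <- matrix(q, k, k)
    diag(counts) <- 0
    perm <- sample.int(k)
    if (m > 0) {
      from <- perm[((seq_len(m) - 1) %% k) + 1]
      to <- perm[(seq_len(m) %% k) + 1]
      for (e in seq_len(m)) counts[from[e], to[e]] <- counts[from[e], to[e]] + 1
    }
    s <- perm[1]
    # Hierholzer: stack-based Eulerian path, random available edge each step
    stack <- integer(n_edges + 1)
    stack[1] <- s
    top <- 1L
    path <- integer(n_edges + 1)
    plen <- 0L
    while (top > 0L) {
      v <- stack[top]
      avail <- which(counts[v, ] > 0L)
      if (length(avail) > 0L) {
        w <- if (length(avail) == 1L) avail else
          sample(avail, 1L, prob = counts[v, avail])
        counts[v, w] <- counts[v, w] - 1L
        top <- top + 1L
        stack[top] <- w
      } else {
        plen <- plen + 1L
        path[plen] <- v
        top <- top - 1L
      }
    }
    seq_nodes <- rev(path[seq_len(plen)])
    if (length(seq_nodes) != k * r)
      stopf("internal error: Eulerian path construction failed")
    labs[seq_nodes]
  })
}

#' Tally ordered cross-condition transitions of a block sequence
#'
#' @param sequence character vector of condition labels.
#' @return A table of counts for each ordered pair `a -> b`, `a != b`.
#' @export
transition_counts <- function(sequence) {
  n <- length(sequence)
  if (n < 2) return(table(character(0)))
  from <- sequence[-n]
  to <- sequence[-1]
  keep <- from != to
  table(paste(from[keep], to[keep], sep = "->"))
}

#' Lay out block onsets for one run
#'
#' The run starts with `lead_trail_fixation_s` of fixation, blocks are
#' separated by uniform jitter in `fixation_jitter_s`, and the run ends with
#' another lead-out fixation. Each block also receives its within-block
#' saccade target schedule via [make_target_sequence()].
#'
#' @param sequence condition label vector from [make_block_sequence()].
#' @param params a [design_params()] object.
#' @param seed integer seed.
#' @return A list of class `run_design`: `blocks` (data.frame with `index`,
#'   `condition`, `size`, `hemifield`, `onset_s`, `duration_s`, and
#'   list-columns `target_times_s`, `target_positions_deg`), `duration_s`,
#'   `n_volumes`, `tr_s`.
#' @export
make_run_timing <- function(sequence, params = design_params(), seed = params$seed) {
  if (length(sequence) == 0) stopf("invalid parameter: empty block sequence")
  n <- length(sequence)
  bd <- params$block_duration_s
  lead <- params$lead_trail_fixation_s
  with_seed(seed, {
    gaps <- if (n > 1) runif(n - 1, params$fixation_jitter_s[1], params$fixation_jitter_s[2]) else numeric(0)
    onsets <- lead + cumsum(c(0, bd + gaps))
    cond <- merge(data.frame(label = sequence, ord = seq_len(n)),
                  params$conditions, by = "label", sort = FALSE)
    cond <- cond[order(cond$ord), ]
    blocks <- data.frame(
      index = seq_len(n),
      condition = sequence,
      size = cond$size,
      hemifield = cond$hemifield,
      onset_s = onsets,
      duration_s = bd,
      stringsAsFactors = FALSE
    )
    tgt <- lapply(seq_len(n), function(b)
      make_target_sequence(blocks[b, ], params,
                           seed = derive_seed(seed, 101L, b)))
    blocks$target_times_s <- lapply(tgt, `[[`, "times_s")
    blocks$target_positions_deg <- lapply(tgt, `[[`, "positions_deg")
    duration <- onsets[n] + bd + lead
    structure(list(blocks = blocks,
                   duration_s = duration,
                   n_volumes = as.integer(ceiling(duration / params$tr_s)),
                   tr_s = params$tr_s),
              class = "run_design")
  })
}

#' Within-block saccade target schedule
#'
#' Six targets per 4 s block (mean rate exactly 1.5 Hz by construction):
#' odd-indexed targets are peripheral (the condition's eccentricity, or for
#' mixed blocks the small/medium/large eccentricities in seeded random
#' order), even-indexed targets return gaze to center. Target times jitter
#' uniformly by ±30% of the mean inter-target interval around a regular
#' grid; the jitter bound keeps times strictly increasing and inside the
#' block.
#'
#' @param block one row of a `run_design` blocks data.frame (needs `size`,
#'   `hemifield`, `duration_s`).
#' @param params a [design_params()] object.
#' @param seed integer seed.
#' @return list with `times_s` (offsets within the block) and
#'   `positions_deg` (signed eccentricities; left hemifield negative).
#' @export
make_target_sequence <- function(block, params = design_params(), seed = params$seed) {
  size <- as.character(block$size)
  hemi <- as.character(block$hemifield)
  if (!size %in% c("small", "medium", "large", "mixed"))
    stopf("invalid parameter: unknown block size '%s'", size)
  ns <- params$saccades_per_block
  bd <- block$duration_s
  ecc <- params$target_eccentricities_deg
  with_seed(seed, {
    mean_iv <- bd / ns
    grid <- (seq_len(ns) - 1) * mean_iv
    times <- grid + runif(ns, -0.3 * mean_iv, 0.3 * mean_iv)
    times[1] <- max(times[1], 0)
    sgn <- if (hemi == "left") -1 else 1
    n_out <- ns / 2
    peripheral <- switch(size,
      small = rep(ecc[["small"]], n_out),
      medium = rep(ecc[["medium"]], n_out),
      large = rep(ecc[["large"]], n_out),
      mixed = sample(unname(ecc[c("small", "medium", "large")]), n_out))
    positions <- numeric(ns)
    positions[seq(1, ns, by = 2)] <- sgn * peripheral
    list(times_s = times, positions_deg = positions)
  })
}

#' Generate a full multi-run experiment design for one subject
#'
#' @param params a [design_params()] object.
#' @param subject_id identifier stored in the design.
#' @param seed integer master seed for this subject.
#' @param runs number of runs (defaults to `params$runs_per_subject`).
#' @return list of class `experiment_design` with `subject_id` and `runs`
#'   (a list of `run_design` objects).
#' @export
make_experiment_design <- function(params = design_params(), subject_id = "sub-01",
                                   seed = params$seed,
                                   runs = params$runs_per_subject) {
  run_list <- lapply(seq_len(runs), function(rr) {
    sq <- make_block_sequence(params, seed = derive_seed(seed, 1L, rr))
    make_run_timing(sq, params, seed = derive_seed(seed, 2L, rr))
  })
  structure(list(subject_id = subject_id, runs = run_list, params = params),
            class = "experiment_design")
}

#' Write a run's events table (BIDS-events dialect TSV)
#'
#' Columns: `onset`, `duration`, `trial_type`, `hemifield`, `target_deg`
#' (comma-joined signed peripheral eccentricities), onsets in seconds from
#' run start.
#'
#' @param run a `run_design` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(run, path) {
  b <- run$blocks
  periph <- vapply(b$target_positions_deg, function(p)
    paste(p[p != 0], collapse = ","), character(1))
  df <- data.frame(onset = b$onset_s, duration = b$duration_s,
                   trial_type = b$size, hemifield = b$hemifield,
                   target_deg = periph, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path file path.
#' @return data.frame with the events columns.
#' @export
read_events_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
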