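# Small fixtures shared across test files; everything is generated in code.

tiny_params <- function(...) design_params(runs_per_subject = 2, ...)

# a short single-block run design, handy for trace-level tests
one_block_run <- function(size = "small", hemifield = "left", seed = 1) {
  p <- design_params()
  blocks <- data.frame(index = 1L, condition = paste(size, hemifield, sep = "_"),
                       size = size, hemifield = hemifield,
                       onset_s = 8, duration_s = 4, stringsAsFactors = FALSE)
  tgt <- make_target_sequence(blocks[1, ], p, seed = seed)
  blocks$target_times_s <- list(tgt$times_s)
  blocks$target_positions_deg <- list(tgt$positions_deg)
  structure(list(blocks = blocks, duration_s = 20,
                 n_volumes = 10L, tr_s = 2), class = "run_design")
}

# small atlas: all eight ROIs at a reduced size on the default grid
small_atlas <- function(size = 60, seed = 5) {
  sizes <- default_roi_sizes()
  sizes[] <- size
  build_atlas(grid_spec(), sizes, seed = seed)
}

# compact experiment for pipeline-scale tests
small_pipeline_config <- function(n_subjects = 3, runs = 3, roi_size = 60,
                                  seed = 42, ...) {
  sizes <- default_roi_sizes()
  sizes[] <- roi_size
  pipeline_config(n_subjects = n_subjects,
                  design = design_params(runs_per_subject = runs),
                  atlas_sizes = sizes,
                  inference = inference_config(n_permutations = 500),
                  do_eye_qc = FALSE,
                  seed = seed, ...)
}
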