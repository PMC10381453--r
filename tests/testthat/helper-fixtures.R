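# Shared fixtures: small, fast synthetic configurations used across tests.
# Full-size studies (the default config) are built only where a test needs
# the complete design.

# A small three-modality configuration: 4 joints x (2+2) samples, coarse
# axes sized so the default SG windows do not apply (tests supply their own
# preprocessing specs).
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_joints = 4L, samples_per_joint_per_class = 2L,
    subgroup_scheme = c(E1 = 0.5, M1 = 0.5),
    replicates_per_sample = 2L,
    modalities = list(
      MIR = list(start = 900, end = 1800, channels = 301L,
                 peaks = data.frame(center = c(1245, 1655),
                                    width = c(20, 20),
                                    base = c(0.8, 1.0),
                                    delta = c(0.15, 0))),
      NIR = list(start = 4500, end = 8400, channels = 261L,
                 peaks = data.frame(center = c(4726, 6900),
                                    width = c(40, 150),
                                    base = c(0.8, 1.0),
                                    delta = c(0.15, 0))),
      Raman = list(start = 800, end = 1800, channels = 334L,
                   peaks = data.frame(center = c(1004, 1448),
                                      width = c(12, 15),
                                      base = c(1.0, 0.8),
                                      delta = c(0.15, 0)))),
    rng_seed = seed), list(...))
  do.call(synth_config, args)
}

# Light preprocessing matching the small axes: smoothing + SNV, full-range
# trim.
small_specs <- function() {
  list(MIR = preprocess_spec(deriv_order = 0L, sg_window = 5L),
       NIR = preprocess_spec(deriv_order = 0L, sg_window = 5L),
       Raman = preprocess_spec(deriv_order = 0L, sg_window = 5L))
}

# Preprocess every block of a study and average replicates; returns the
# named list of sample-level blocks.
prep_study <- function(study, specs) {
  out <- lapply(names(study$blocks), function(nm)
    average_replicates(preprocess_block(study$blocks[[nm]], specs[[nm]])))
  names(out) <- names(study$blocks)
  out
}

# Design rows aligned to a sample-level block's row order.
aligned_design <- function(study, blocks) {
  keys <- blocks[[1]]$row_keys
  study$design[match(keys$sample_id, study$design$sample_id), ]
}

# A deterministic toy block: rows are index ramps plus offsets.
toy_block <- function(n = 4, p = 10, modality = "TOY") {
  X <- outer(seq_len(n), seq_len(p), function(i, j) i + j / 10)
  spectral_block(modality, seq_len(p), X,
                 data.frame(sample_id = paste0("s", seq_len(n)),
                            replicate = 1L))
}

# The default-scale study used by the slower integration tests, built once
# per test run.
default_study_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- generate_study(synth_config(rng_seed = 42L))
      st <- drop_sample(st, st$design$sample_id[st$design$class == 1L][1])
      prep <- prep_study(st, default_preprocess_specs())
      cache <<- list(study = st, prep = prep,
                     design = aligned_design(st, prep))
    }
    cache
  }
})
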