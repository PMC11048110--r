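# Shared fixtures: small, fast cohorts and model geometries used across the
# unit tests. Everything is generated in code under fixed seeds.

# Desk-scale simulator settings: 8 channels at 64 Hz keep encoder passes
# cheap while preserving the full architecture (pools 4 and 8 leave two time
# bins; all three temporal kernels fit in the 64-sample epoch).
tiny_sim <- function(n_subjects = 4, trials = 50, seed = 7, ratio_amp = 2, ...) {
  sim_config(n_subjects = n_subjects, trials_per_subject = trials,
             sfreq = 64, n_channels = 8,
             erp_amplitude_mean = 5 * ratio_amp,
             erp_amplitude_subject_sd = ratio_amp,
             noise_sd = 5, seed = seed, ...)
}

tiny_cohort <- function(...) make_cohort(tiny_sim(...))

tiny_encoder_cfg <- function(...) encoder_config(...)

tiny_train_cfg <- function(epochs = 2, seed = 11, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

# Minimal geometry for gradient checks: 4 channels x 32 samples.
fd_encoder <- function(seed = 3, variant = "incepa", dropout = 0) {
  cfg <- encoder_config(temporal_kernels_s = c(0.06, 0.03),
                        filters_per_branch = 2, se_reduction = 2,
                        depth_multiplier = 2, eca_kernel = 3, sep_kernel = 4,
                        pool1 = 2, pool2 = 2, dropout = dropout)
  build_encoder(cfg, n_channels = 4, n_samples = 32, sfreq = 100,
                seed = seed, variant = variant)
}

# Random feature batches shaped like encoder output.
random_features <- function(n, seed = 1, dim = 1024) {
  withr::with_seed(seed, matrix(rnorm(n * dim), n, dim))
}
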