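# Synthetic multi-subject RSVP-ERP cohort generator.
#
# Emulates the statistical structure the decoder assumes: rare targets
# (default 1 : 24), a P300-like positive deflection present only in target
# trials with subject-specific amplitude/latency/topography, and colored
# (AR(1)) background noise independent per channel. It deliberately omits
# artifacts (blinks, EMG), overlapping stimulus responses and measured noise
# spectra -- the simulator exists to exercise cross-subject transfer, not
# artifact robustness.

#' Configuration for the synthetic RSVP cohort simulator
#'
#' Defaults encode the study conditions: 1 target per 25 trials, 250 Hz,
#' 1-second epochs, 16 channels, a P300-like bump at 350 ms (80 ms Gaussian
#' width) with 30 ms between-subject and 20 ms within-subject latency jitter,
#' and AR(1) channel noise with coefficient 0.95. `noise_sd` is the standard
#' deviation of the white noise driving the AR(1) process; the stationary
#' background RMS is `noise_sd / sqrt(1 - ar_coeff^2)`. Amplitudes are in
#' microvolts: the default 5 uV bump against a 5 uV driving noise matches the
#' amplitude-to-noise ratio of 1 used throughout the package's synthetic
#' experiments.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param trials_per_subject trials simulated per subject.
#' @param target_ratio fraction of target trials (default 1/25).
#' @param sfreq sampling rate in Hz.
#' @param window_s epoch duration in seconds.
#' @param n_channels number of channels.
#' @param erp_amplitude_mean mean ERP peak amplitude in microvolts.
#' @param erp_amplitude_subject_sd between-subject sd of the peak amplitude.
#' @param erp_latency_mean_s mean ERP latency (s, relative to epoch start).
#' @param erp_latency_subject_sd_s between-subject latency sd (s).
#' @param erp_latency_trial_sd_s within-subject trial-to-trial latency sd (s).
#' @param erp_width_s Gaussian temporal width (sd) of the bump (s).
#' @param noise_sd sd of the white noise driving the AR(1) background.
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param topography_perturb_sd per-subject perturbation sd of the unit-norm
#'   base topography.
#' @param seed root seed; subject `i` uses the derived stream `seed + i`.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10,
                       trials_per_subject = 500,
                       target_ratio = 1 / 25,
                       sfreq = 250,
                       window_s = 1.0,
                       n_channels = 16,
                       erp_amplitude_mean = 5,
                       erp_amplitude_subject_sd = 1,
                       erp_latency_mean_s = 0.35,
                       erp_latency_subject_sd_s = 0.03,
                       erp_latency_trial_sd_s = 0.02,
                       erp_width_s = 0.08,
                       noise_sd = 5,
                       ar_coeff = 0.95,
                       topography_perturb_sd = 0.1,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 1)
    stop_validation("n_subjects must be a positive integer")
  if (!is_count(cfg$trials_per_subject) || cfg$trials_per_subject < 1)
    stop_validation("trials_per_subject must be a positive integer")
  if (!is_scalar_num(cfg$target_ratio) || cfg$target_ratio <= 0 || cfg$target_ratio >= 0.5)
    stop_validation("target_ratio must lie in (0, 0.5)")
  if (!is_scalar_num(cfg$sfreq) || cfg$sfreq <= 0)
    stop_validation("sfreq must be positive")
  if (!is_scalar_num(cfg$window_s) || cfg$window_s <= 0)
    stop_validation("window_s must be positive")
  if (!is_count(cfg$n_channels) || cfg$n_channels < 1)
    stop_validation("n_channels must be a positive integer")
  for (f in c("erp_amplitude_subject_sd", "erp_latency_subject_sd_s",
              "erp_latency_trial_sd_s", "noise_sd", "topography_perturb_sd"))
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] < 0)
      stop_validation(f, " must be >= 0")
  if (!is_scalar_num(cfg$erp_width_s) || cfg$erp_width_s <= 0)
    stop_validation("erp_width_s must be positive")
  if (!is_scalar_num(cfg$ar_coeff) || cfg$ar_coeff < 0 || cfg$ar_coeff >= 1)
    stop_validation("ar_coeff must lie in [0, 1)")
  spread <- 3 * (cfg$erp_latency_subject_sd_s + cfg$erp_latency_trial_sd_s)
  if (cfg$erp_latency_mean_s - spread < 0 || cfg$erp_latency_mean_s + spread > cfg$window_s)
    stop_validation("erp_latency_mean_s +/- 3*(subject_sd + trial_sd) must lie inside the window")
  if (!is_count(cfg$seed)) stop_validation("seed must be an integer")
  cfg
}

#' Base scalp topography used by the simulator
#'
#' A raised-cosine loading peaking at a "Pz-like" centro-parietal channel
#' (index `round(n_channels * 5/8)`, 1-based) with half-width
#' `n_channels / 4` channels, zero elsewhere, normalized to unit Euclidean
#' norm. Any smooth unimodal loading would do; this one is fixed so that
#' simulated cohorts are reproducible and the peak channel is known in tests.
#'
#' @param n_channels number of channels.
#' @return unit-norm numeric vector of channel weights.
#' @export
base_topography <- function(n_channels) {
  peak <- round(n_channels * 5 / 8)
  halfwidth <- max(1, n_channels / 4)
  idx <- seq_len(n_channels)
  w <- 0.5 * (1 + cos(pi * (idx - peak) / halfwidth))
  w[abs(idx - peak) > halfwidth] <- 0
  w / sqrt(sum(w^2))
}

# AR(1) epochs: x_t = a x_{t-1} + e_t, e_t ~ N(0, sd^2), started from the
# stationary distribution so every sample has the stationary variance.
ar1_noise <- function(n_trials, n_channels, n_samples, sd, a) {
  x <- array(rnorm(n_trials * n_channels * n_samples), c(n_trials, n_channels, n_samples))
  if (sd == 0) return(array(0, dim(x)))
  if (a > 0) {
    x[, , 1L] <- x[, , 1L] / sqrt(1 - a^2)
    for (t in 2:n_samples) x[, , t] <- a * x[, , t - 1L] + x[, , t]
  }
  x * sd
}

#' Simulate one subject's epoched RSVP-EEG
#'
#' Background noise is AR(1) per channel (coefficient `ar_coeff`, driving
#' white-noise sd `noise_sd`). Target trials additionally receive a Gaussian
#' bump `A_s * exp(-(t - L)^2 / (2 * erp_width_s^2))` projected onto the
#' subject's topography, where the amplitude `A_s` and mean latency `L_s` are
#' drawn once per subject and each trial adds latency jitter. The number of
#' targets is `round(trials_per_subject * target_ratio)`, placed uniformly at
#' random. The result is fully determined by `(config$seed, subject_index)`:
#' a subject's data does not depend on how many other subjects are simulated.
#'
#' @param config a [sim_config()].
#' @param subject_index 1-based subject index within the cohort.
#' @return an [epoch_set()] with subject id `S<index>`.
#' @export
make_subject <- function(config, subject_index) {
  config <- validate_sim_config(config)
  if (!is_count(subject_index) || subject_index < 1)
    stop_validation("subject_index must be a positive integer")
  n <- config$trials_per_subject
  nc <- config$n_channels
  ns <- max(1L, floor(config$window_s * config$sfreq))
  with_seed(config$seed + subject_index, {
    # subject-level draws first: amplitude, latency, topography perturbation
    amp <- rnorm(1, config$erp_amplitude_mean, config$erp_amplitude_subject_sd)
    lat <- rnorm(1, config$erp_latency_mean_s, config$erp_latency_subject_sd_s)
    topo <- base_topography(nc) + rnorm(nc, 0, config$topography_perturb_sd)
    topo <- topo / sqrt(sum(topo^2))
    n_target <- round(n * config$target_ratio)
    target_idx <- sample.int(n, n_target)
    labels <- integer(n)
    labels[target_idx] <- 1L
    data <- ar1_noise(n, nc, ns, config$noise_sd, config$ar_coeff)
    tgrid <- (seq_len(ns) - 1L) / config$sfreq
    for (i in target_idx) {
      l_i <- lat + rnorm(1, 0, config$erp_latency_trial_sd_s)
      bump <- amp * exp(-(tgrid - l_i)^2 / (2 * config$erp_width_s^2))
      data[i, , ] <- data[i, , ] + outer(topo, bump)
    }
    epoch_set(data, labels,
              subject_id = sprintf("S%02d", subject_index),
              sfreq = config$sfreq,
              channel_names = sprintf("ch%02d", seq_len(nc)))
  })
}

#' Simulate a multi-subject cohort
#'
#' @param config a [sim_config()] with `n_subjects >= 2` (episodic training
#'   needs at least two subjects).
#' @return a `subject_collection` of `n_subjects` independent subjects.
#' @export
make_cohort <- function(config) {
  config <- validate_sim_config(config)
  if (config$n_subjects < 2)
    stop_validation("n_subjects must be >= 2 for episodic training")
  subject_collection(lapply(seq_len(config$n_subjects),
                            function(i) make_subject(config, i)))
}
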