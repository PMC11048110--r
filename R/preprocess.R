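# Preprocessing: zero-phase Butterworth bandpass, window slicing, integer
# decimation and train-statistics-only standardization.

#' Preprocessing configuration
#'
#' Defaults follow the standard RSVP-ERP pipeline: a 2-30 Hz 4th-order
#' Butterworth bandpass (applied forward-backward, i.e. zero-phase, so the
#' ERP peak latency is not shifted), no resampling, the full epoch window and
#' per-channel standardization fitted on training subjects only.
#'
#' @param band_low lower passband edge (Hz).
#' @param band_high upper passband edge (Hz); must stay below the Nyquist
#'   frequency of the data it is applied to.
#' @param order Butterworth design order (even, `>= 2`). `order = 4`
#'   reproduces the conventional "4th-order Butterworth bandpass" of
#'   `butter(4, c(low, high))`; the forward-backward pass doubles the
#'   effective attenuation.
#' @param resample_to target rate in Hz (integer decimation of the input
#'   rate), or `NULL` to keep the input rate. Decimation relies on the
#'   preceding bandpass for anti-aliasing, so it requires
#'   `band_high < resample_to / 2`.
#' @param window numeric `c(start_s, end_s)` half-open window relative to
#'   epoch start, or `NULL` for the full epoch.
#' @param standardize logical; whether pipelines built on this config should
#'   z-score channels using training-set statistics.
#' @return a validated `preproc_config` list.
#' @export
preproc_config <- function(band_low = 2, band_high = 30, order = 4,
                           resample_to = NULL, window = NULL,
                           standardize = TRUE) {
  cfg <- list(band_low = band_low, band_high = band_high, order = order,
              resample_to = resample_to, window = window,
              standardize = isTRUE(standardize))
  class(cfg) <- "preproc_config"
  validate_preproc_config(cfg)
}

validate_preproc_config <- function(cfg) {
  if (!is_scalar_num(cfg$band_low) || !is_scalar_num(cfg$band_high) ||
      cfg$band_low <= 0 || cfg$band_low >= cfg$band_high)
    stop_validation("need 0 < band_low < band_high")
  if (!is_count(cfg$order) || cfg$order < 2 || cfg$order %% 2 != 0)
    stop_validation("order must be an even integer >= 2")
  if (!is.null(cfg$resample_to)) {
    if (!is_scalar_num(cfg$resample_to) || cfg$resample_to <= 0)
      stop_validation("resample_to must be positive or NULL")
    if (cfg$band_high >= cfg$resample_to / 2)
      stop_validation("band_high must be below the post-resampling Nyquist (resample_to/2)")
  }
  if (!is.null(cfg$window)) {
    if (length(cfg$window) != 2L || !all(is.finite(cfg$window)))
      stop_validation("window must be c(start_s, end_s)")
    if (cfg$window[2L] <= cfg$window[1L] || cfg$window[1L] < 0)
      stop_validation("window must satisfy 0 <= start_s < end_s")
  }
  cfg
}

# Zero-phase IIR filtering of every column of a matrix, with odd-reflection
# padding at both ends (three filter lengths) to suppress edge transients.
filtfilt_mat <- function(b, a, x) {
  n <- nrow(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  one_pass <- function(x) {
    top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[pad + 1L - seq_len(pad) + 1L, , drop = FALSE]
    bot <- 2 * x[rep(n, pad), , drop = FALSE] - x[n - seq_len(pad), , drop = FALSE]
    y <- .iir_cols(b, a, rbind(top, x, bot))
    y[pad + seq_len(n), , drop = FALSE]
  }
  fwd <- one_pass(x)
  bwd <- one_pass(fwd[n:1L, , drop = FALSE])
  bwd[n:1L, , drop = FALSE]
}

#' Zero-phase Butterworth bandpass of an epoch set
#'
#' Applies the configured bandpass independently per trial and channel,
#' forward and backward (zero phase). Shape and labels are preserved.
#'
#' @param epochs an [epoch_set()].
#' @param config a [preproc_config()].
#' @return the filtered `epoch_set`.
#' @export
bandpass <- function(epochs, config) {
  epochs <- validate_epoch_set(epochs)
  config <- validate_preproc_config(config)
  nyq <- epochs$sfreq / 2
  if (config$band_high >= nyq)
    stop_validation("band_high (", config$band_high, " Hz) must be below Nyquist (",
                    nyq, " Hz)")
  bt <- signal::butter(config$order, c(config$band_low, config$band_high) / nyq,
                       type = "pass")
  d <- dim(epochs$data)
  # one big (samples x trials*channels) matrix so the C filter loop does the work
  x <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = d[3L])
  y <- filtfilt_mat(bt$b, bt$a, x)
  epochs$data <- aperm(array(y, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  epochs
}

#' Slice a half-open time window out of an epoch set
#'
#' Keeps samples in `[start_s, end_s)`; the sample index of a time `t` is
#' `floor(t * sfreq)` (0-based).
#'
#' @param epochs an [epoch_set()].
#' @param window numeric `c(start_s, end_s)`.
#' @return the sliced `epoch_set`.
#' @export
slice_window <- function(epochs, window) {
  epochs <- validate_epoch_set(epochs)
  if (length(window) != 2L || window[2L] <= window[1L] || window[1L] < 0)
    stop_validation("window must satisfy 0 <= start_s < end_s")
  ns <- dim(epochs$data)[3L]
  i0 <- floor(window[1L] * epochs$sfreq)        # 0-based, inclusive
  i1 <- floor(window[2L] * epochs$sfreq) - 1L   # 0-based, inclusive
  if (i0 >= ns || i1 >= ns)
    stop_validation("window extends past the epoch duration")
  if (i1 < i0) stop_validation("window contains no samples")
  epochs$data <- epochs$data[, , (i0 + 1L):(i1 + 1L), drop = FALSE]
  epochs
}

# Integer decimation; assumes the signal is already band-limited below the
# new Nyquist rate (enforced by preproc_config).
decimate_epochs <- function(epochs, resample_to) {
  factor <- epochs$sfreq / resample_to
  if (abs(factor - round(factor)) > 1e-9)
    stop_validation("resample_to must divide sfreq (integer decimation); got ",
                    epochs$sfreq, " -> ", resample_to)
  factor <- as.integer(round(factor))
  if (factor > 1L) {
    ns <- dim(epochs$data)[3L]
    keep <- seq(1L, ns, by = factor)
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$sfreq <- epochs$sfreq / factor
  }
  epochs
}

#' Apply windowing, bandpass filtering and decimation to every subject
#'
#' Runs the stateless part of the preprocessing pipeline (slice, filter,
#' decimate) per subject. Standardization is stateful (its statistics must
#' come from training subjects only) and is applied separately with
#' [standardize()].
#'
#' @param coll a `subject_collection`.
#' @param config a [preproc_config()].
#' @return the preprocessed `subject_collection`.
#' @export
preprocess_collection <- function(coll, config) {
  config <- validate_preproc_config(config)
  out <- lapply(unclass(coll), function(es) {
    if (!is.null(config$window)) es <- slice_window(es, config$window)
    es <- bandpass(es, config)
    if (!is.null(config$resample_to)) es <- decimate_epochs(es, config$resample_to)
    es
  })
  subject_collection(out)
}

#' Per-channel z-scoring with statistics from the training set only
#'
#' Channel means and standard deviations are computed on `train` (pooled over
#' its subjects, trials and samples) and applied unchanged to `apply_to`.
#' This is the zero-calibration hygiene point of the pipeline: statistics of
#' held-out data are never consulted.
#'
#' @param train a `subject_collection` supplying the statistics.
#' @param apply_to a `subject_collection` to transform (defaults to `train`).
#' @return `apply_to` with each channel centered and scaled by the training
#'   statistics.
#' @export
standardize <- function(train, apply_to = train) {
  if (!identical(train[[1L]]$channel_names, apply_to[[1L]]$channel_names))
    stop_validation("channel sets of train and apply_to differ")
  nc <- dim(train[[1L]]$data)[2L]
  acc_n <- 0; acc_sum <- numeric(nc); acc_sq <- numeric(nc)
  for (es in train) {
    d <- dim(es$data)
    m <- matrix(aperm(es$data, c(2L, 1L, 3L)), nrow = d[2L])  # channels x (trials*samples)
    acc_sum <- acc_sum + rowSums(m)
    acc_sq <- acc_sq + rowSums(m^2)
    acc_n <- acc_n + ncol(m)
  }
  mu <- acc_sum / acc_n
  sd <- sqrt(pmax(acc_sq / acc_n - mu^2, 0))
  if (any(sd == 0))
    stop_validation("zero-variance channel: ",
                    train[[1L]]$channel_names[which(sd == 0)[1L]])
  out <- lapply(unclass(apply_to), function(es) {
    d <- dim(es$data)
    es$data <- (es$data - rep(mu, each = d[1L])) / rep(sd, each = d[1L])
    es
  })
  subject_collection(out)
}
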