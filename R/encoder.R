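# R-side surface of the convolutional encoder: configuration, seeded
# construction, and the encode operation mapping epochs to 1024-dimensional
# batch-normalized feature vectors.

#' Encoder configuration
#'
#' The encoder is a two-block convolutional network in the EEGNet lineage.
#' Block 1 runs three parallel temporal convolutions (kernel durations
#' `temporal_kernels_s`, converted to odd sample counts at build time),
#' recalibrates the concatenated maps with a squeeze-and-excitation block,
#' and mixes channels with a depthwise spatial convolution. Block 2 applies
#' a depthwise temporal convolution with efficient channel attention in
#' place of a pointwise convolution. A single linear head maps the flattened
#' maps to a 1024-dimensional feature vector followed by batch
#' normalization. The feature dimension is fixed at 1024.
#'
#' @param temporal_kernels_s kernel durations in seconds, one per branch.
#' @param filters_per_branch temporal filters per branch.
#' @param se_reduction squeeze-and-excitation bottleneck reduction factor.
#' @param depth_multiplier spatial depthwise multiplier.
#' @param eca_kernel efficient-channel-attention kernel (odd).
#' @param sep_kernel block-2 depthwise temporal kernel length in samples;
#'   must not exceed the pooled epoch length at build time.
#' @param pool1,pool2 average-pooling factors of blocks 1 and 2.
#' @param dropout dropout fraction used in training mode.
#' @param out_dim output feature dimension; fixed at 1024.
#' @return a validated `encoder_config` list.
#' @export
encoder_config <- function(temporal_kernels_s = c(0.256, 0.128, 0.064),
                           filters_per_branch = 8,
                           se_reduction = 4,
                           depth_multiplier = 2,
                           eca_kernel = 3,
                           sep_kernel = 16,
                           pool1 = 4,
                           pool2 = 8,
                           dropout = 0.25,
                           out_dim = 1024) {
  cfg <- as.list(environment())
  class(cfg) <- "encoder_config"
  validate_encoder_config(cfg)
}

validate_encoder_config <- function(cfg) {
  if (!identical(as.integer(cfg$out_dim), 1024L))
    stop_validation("out_dim is fixed at 1024")
  if (!is.numeric(cfg$temporal_kernels_s) || length(cfg$temporal_kernels_s) < 1 ||
      any(cfg$temporal_kernels_s <= 0))
    stop_validation("temporal_kernels_s must be positive durations")
  if (!is_count(cfg$eca_kernel) || cfg$eca_kernel %% 2L != 1L)
    stop_validation("eca_kernel must be an odd integer")
  for (f in c("filters_per_branch", "se_reduction", "depth_multiplier",
              "sep_kernel", "pool1", "pool2"))
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1)
      stop_validation(f, " must be a positive integer")
  if (!is_scalar_num(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1)
    stop_validation("dropout must lie in [0, 1)")
  cfg
}

#' Build a seeded encoder
#'
#' Converts kernel durations to odd sample counts for the given sampling
#' rate, validates that every kernel fits in the epoch, and initializes all
#' weights (He-style scaled Gaussians; batch-norm scale 1 / shift 0)
#' deterministically from `seed`.
#'
#' @param config an [encoder_config()].
#' @param n_channels,n_samples input epoch geometry.
#' @param sfreq sampling rate of the epochs the encoder will see (Hz).
#' @param seed integer; two builds with the same seed have identical weights.
#' @param variant `"incepa"` (squeeze-and-excitation + efficient channel
#'   attention active) or `"plain"` (both attention blocks disabled).
#' @return an `encoder` object (weights, batch-norm buffers, geometry); its
#'   `n_params` field reports the trainable parameter count.
#' @export
build_encoder <- function(config, n_channels, n_samples, sfreq, seed = 1,
                          variant = c("incepa", "plain")) {
  config <- validate_encoder_config(config)
  variant <- match.arg(variant)
  if (!is_count(n_channels) || n_channels < 1) stop_validation("n_channels must be a positive integer")
  if (!is_count(n_samples) || n_samples < 1) stop_validation("n_samples must be a positive integer")
  taps <- vapply(config$temporal_kernels_s, function(s) round_to_odd(s * sfreq), integer(1))
  if (any(taps > n_samples))
    stop_validation("temporal kernel of ", max(taps), " samples exceeds the epoch length (",
                    n_samples, " samples)")
  t1 <- n_samples %/% config$pool1
  t2 <- t1 %/% config$pool2
  if (t2 < 1)
    stop_validation("pooling (", config$pool1, ", ", config$pool2,
                    ") reduces ", n_samples, " samples to zero")
  if (config$sep_kernel > t1)
    stop_validation("sep_kernel (", config$sep_kernel,
                    ") exceeds the pooled epoch length (", t1, ")")
  b <- length(taps)
  f1 <- config$filters_per_branch
  m1 <- b * f1
  h <- max(1L, m1 %/% config$se_reduction)
  dm <- config$depth_multiplier
  m2 <- m1 * dm
  flat <- m2 * t2
  params <- with_seed(seed, list(
    wt = lapply(taps, function(k) matrix(rnorm(k * f1, 0, sqrt(2 / k)), k, f1)),
    se_w1 = matrix(rnorm(m1 * h, 0, sqrt(2 / m1)), m1, h),
    se_b1 = numeric(h),
    se_w2 = matrix(rnorm(h * m1, 0, sqrt(2 / h)), h, m1),
    se_b2 = numeric(m1),
    wsp = array(rnorm(n_channels * dm * m1, 0, sqrt(2 / n_channels)),
                c(n_channels, dm, m1)),
    bn1_gamma = rep(1, m2), bn1_beta = numeric(m2),
    wdt = matrix(rnorm(config$sep_kernel * m2, 0, sqrt(2 / config$sep_kernel)),
                 config$sep_kernel, m2),
    eca_w = rnorm(config$eca_kernel, 0, sqrt(2 / config$eca_kernel)),
    bn2_gamma = rep(1, m2), bn2_beta = numeric(m2),
    wd = matrix(rnorm(flat * config$out_dim, 0, sqrt(2 / flat)), flat, config$out_dim),
    bd = numeric(config$out_dim),
    bn3_gamma = rep(1, config$out_dim), bn3_beta = numeric(config$out_dim)
  ))
  buffers <- list(
    bn1_rm = numeric(m2), bn1_rv = rep(1, m2),
    bn2_rm = numeric(m2), bn2_rv = rep(1, m2),
    bn3_rm = numeric(config$out_dim), bn3_rv = rep(1, config$out_dim)
  )
  hyper <- list(pool1 = config$pool1, pool2 = config$pool2,
                dropout = config$dropout,
                use_se = variant == "incepa", use_eca = variant == "incepa")
  enc <- list(config = config, params = params, buffers = buffers,
              hyper = hyper, variant = variant,
              n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples), sfreq = sfreq,
              taps = taps,
              n_params = sum(vapply(rapply(params, length, how = "unlist"),
                                    identity, numeric(1))))
  class(enc) <- "encoder"
  enc
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("<encoder> %s: %d channels x %d samples @ %g Hz -> %d features, %d trainable parameters\n",
              x$variant, x$n_channels, x$n_samples, x$sfreq,
              x$config$out_dim, as.integer(x$n_params)))
  invisible(x)
}

# Low-level forward pass on a (trials, channels, samples) array.
# Returns features (n x 1024), batch-norm buffer updates and (optionally)
# the backward cache. `dropout_seed` only matters in training mode.
enc_run <- function(enc, data, training, want_cache = FALSE, dropout_seed = 0,
                    fixed_stats = NULL) {
  d <- dim(data)
  if (d[2L] != enc$n_channels || d[3L] != enc$n_samples)
    stop_shape("encoder expects (", enc$n_channels, " channels x ", enc$n_samples,
               " samples), got (", d[2L], " x ", d[3L], ")")
  x <- aperm(data, c(3L, 2L, 1L))   # (samples, channels, trials)
  .enc_forward(c(enc$params, enc$buffers), x, enc$hyper, training, want_cache,
               as.double(dropout_seed), fixed_stats)
}

enc_grad <- function(enc, cache, d_features) {
  .enc_backward(cache, c(enc$params, enc$buffers), d_features)
}

#' Encode an epoch set into a feature batch
#'
#' Maps every trial to a 1024-dimensional feature vector, in input order. In
#' training mode the final batch norm uses the batch's own statistics (so
#' per-column means are ~0 for reasonably sized batches at initialization);
#' in evaluation mode it uses the encoder's running statistics and the pass
#' is fully deterministic (dropout off). `encode()` never mutates the
#' encoder; running statistics are maintained by the training loop.
#'
#' @param encoder an encoder from [build_encoder()] or a fitted model's
#'   `$encoder`.
#' @param epochs an [epoch_set()] matching the encoder geometry.
#' @param training_mode logical.
#' @return a `feature_batch`: list with `features` (n x 1024 matrix),
#'   `labels` and `subject_id` carried from the input.
#' @export
encode <- function(encoder, epochs, training_mode = FALSE) {
  epochs <- validate_epoch_set(epochs)
  seed <- if (training_mode) sample.int(.Machine$integer.max, 1L) else 0
  out <- enc_run(encoder, epochs$data, training_mode, want_cache = FALSE,
                 dropout_seed = seed)
  structure(list(features = out$features, labels = epochs$labels,
                 subject_id = epochs$subject_id),
            class = "feature_batch")
}
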