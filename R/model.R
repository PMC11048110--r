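# The full model: convolutional encoder + hybrid-attention prototype head,
# with checkpointing and the shared forward machinery used by training and
# zero-calibration evaluation.

#' Assemble an untrained model
#'
#' Combines a seeded encoder with the prototype head's trainable pieces: the
#' `1024 x 1024` linear map of the subject-level attention and the small
#' 1-d convolution of the feature-level attention. Both attention nets are
#' initialized near zero so that, at the start of training, subject weights
#' are almost uniform and feature weights almost flat -- the configuration in
#' which the model coincides with a plain prototype network.
#'
#' @param encoder_cfg an [encoder_config()].
#' @param n_channels,n_samples,sfreq input geometry.
#' @param seed integer controlling all weight initialization.
#' @param feature_attention,subject_attention logical ablation flags.
#' @param encoder `"incepa"` or `"plain"` encoder variant.
#' @return a `pronet_model`.
#' @export
build_model <- function(encoder_cfg = encoder_config(), n_channels, n_samples,
                        sfreq, seed = 1, feature_attention = TRUE,
                        subject_attention = TRUE,
                        encoder = c("incepa", "plain")) {
  encoder <- match.arg(encoder)
  enc <- build_encoder(encoder_cfg, n_channels, n_samples, sfreq, seed = seed,
                       variant = encoder)
  dim <- encoder_cfg$out_dim
  fa_len <- 9L
  proto <- with_seed(seed + 1L, list(
    G = matrix(rnorm(dim * dim, 0, 0.1 / sqrt(dim)), dim, dim),
    fa_w = rnorm(fa_len, 0, 0.1),
    fa_b = 0
  ))
  structure(list(encoder = enc, proto = proto,
                 feature_attention = isTRUE(feature_attention),
                 subject_attention = isTRUE(subject_attention),
                 seed = seed),
            class = "pronet_model")
}

#' @export
print.pronet_model <- function(x, ...) {
  cat(sprintf("<pronet_model> encoder=%s  feature_attention=%s  subject_attention=%s\n",
              x$encoder$variant, x$feature_attention, x$subject_attention))
  print(x$encoder)
  invisible(x)
}

#' Save a model checkpoint
#'
#' A single file containing the full model (weights, batch-norm running
#' statistics, configuration and ablation flags); [load_checkpoint()]
#' restores it exactly.
#'
#' @param model a `pronet_model`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pronet_model"))
  saveRDS(list(format = "protoerp-checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `pronet_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_format("not a protoerp checkpoint: ", path))
  if (!is.list(payload) || !identical(payload$format, "protoerp-checkpoint"))
    stop_format("not a protoerp checkpoint: ", path)
  payload$model
}

# Per-subject class-mean features of a support collection, encoder in the
# requested mode. Returns the (m, 2, dim) class-mean array, the per-subject
# representative features (average of the two class means), the unweighted
# class means across subjects, and the feature-attention scores.
support_state <- function(model, support, training = FALSE, features = NULL) {
  ids <- subject_ids(support)
  m <- length(ids)
  dim <- model$encoder$config$out_dim
  class_means <- array(0, c(m, 2L, dim))
  for (i in seq_len(m)) {
    es <- support[[i]]
    f <- if (is.null(features)) encode(model$encoder, es, training_mode = training)$features
         else features[[i]]
    for (k in 0:1) {
      rows <- which(es$labels == k)
      if (length(rows) == 0L)
        stop_validation("support subject ", es$subject_id,
                        " has no trials of class ", k)
      class_means[i, k + 1L, ] <- colMeans(f[rows, , drop = FALSE])
    }
  }
  subject_means <- (class_means[, 1L, , drop = FALSE][, 1L, , drop = TRUE] +
                    class_means[, 2L, , drop = FALSE][, 1L, , drop = TRUE]) / 2
  if (m == 1L) subject_means <- matrix(subject_means, nrow = 1L)
  c0 <- colMeans(matrix(class_means[, 1L, ], nrow = m))
  c1 <- colMeans(matrix(class_means[, 2L, ], nrow = m))
  z <- feature_attention(c0, c1, model$proto$fa_w, model$proto$fa_b,
                         enabled = model$feature_attention)
  list(ids = ids, class_means = class_means, subject_means = subject_means,
       c0 = c0, c1 = c1, z = z)
}

# Subject-attention weights for a whole query feature matrix at once:
# returns alpha as an (n_queries x m) matrix.
alpha_matrix <- function(model, state, fq) {
  m <- nrow(state$subject_means)
  n <- nrow(fq)
  if (!model$subject_attention || m == 1L)
    return(matrix(1 / m, n, m))
  gu <- state$subject_means %*% t(model$proto$G)   # m x dim
  gq <- fq %*% t(model$proto$G)                    # n x dim
  e <- matrix(0, n, m)
  for (i in seq_len(m))
    e[, i] <- rowSums(tanh(gq * rep(gu[i, ], each = n)))
  e <- exp(e - apply(e, 1L, max))
  e / rowSums(e)
}

# Nearest-prototype classification of a feature matrix under a support
# state; prototypes are per-query when subject attention is on.
classify_with_state <- function(model, state, fq) {
  alpha <- alpha_matrix(model, state, fq)
  m <- nrow(state$subject_means)
  dim <- ncol(fq)
  m0 <- matrix(state$class_means[, 1L, ], nrow = m)
  m1 <- matrix(state$class_means[, 2L, ], nrow = m)
  p0 <- alpha %*% m0                               # n x dim
  p1 <- alpha %*% m1
  d0 <- as.vector((fq - p0)^2 %*% state$z$z0)
  d1 <- as.vector((fq - p1)^2 %*% state$z$z1)
  probs <- class_probabilities(d0, d1)
  list(labels = as.integer(d1 < d0), probs = probs,
       distances = cbind(d0 = d0, d1 = d1), alpha = alpha)
}
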