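# Prototype-network core: class prototypes as subject-attention-weighted
# means of support-subject class features, feature-attention-weighted
# distances, probability mapping and the two loss terms.
#
# Conventions fixed here (and relied on by the tests):
#   * feature dimension is 1024 throughout;
#   * attention score vectors z_k are nonnegative with mean 1, so disabling
#     feature attention (z = 1) recovers plain squared Euclidean distance;
#   * subject weights alpha lie on the simplex (sum 1); uniform alpha
#     recovers the unweighted prototype mean;
#   * class probabilities use the NEGATIVE-distance softmax, so the nearer
#     prototype gets the larger probability;
#   * classification ties break toward class 0 (nontarget).

FEATURE_DIM <- 1024L

#' Subject-level attention weights for one query feature
#'
#' Scores each support subject `k` by
#' `e_k = sum_j tanh( (G u_k)_j * (G q)_j )`, where `u_k` is the subject's
#' representative feature, `q` the query feature and `G` a learned linear
#' map, then returns `alpha = softmax(e)`. With `enabled = FALSE` the weights
#' are uniform, which reduces the attention-weighted prototype to the plain
#' across-subject mean.
#'
#' @param support_means matrix `(n_subjects x 1024)` of per-subject
#'   representative features (here: the average of the subject's two class
#'   means).
#' @param query_feature numeric vector of length 1024.
#' @param g `1024 x 1024` matrix of the linear map, or `NULL` when disabled.
#' @param enabled logical; `FALSE` yields uniform weights.
#' @return numeric vector `alpha` (length `n_subjects`, sums to 1).
#' @export
subject_attention <- function(support_means, query_feature, g, enabled = TRUE) {
  support_means <- as.matrix(support_means)
  m <- nrow(support_means)
  if (m < 1L) stop_shape("need at least one support subject")
  if (!enabled) return(rep(1 / m, m))
  if (ncol(support_means) != length(query_feature))
    stop_shape("query feature length ", length(query_feature),
               " does not match support feature dim ", ncol(support_means))
  if (!is.matrix(g) || nrow(g) != ncol(support_means) || ncol(g) != ncol(support_means))
    stop_shape("g must be a ", ncol(support_means), " x ", ncol(support_means), " matrix")
  gq <- drop(g %*% query_feature)
  gu <- support_means %*% t(g)               # n_subjects x 1024, rows G u_k
  e <- rowSums(tanh(gu * rep(gq, each = m)))
  softmax(e)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Attention-weighted class prototypes
#'
#' `p_k = sum_i alpha_i * mean_feature(subject i, class k)`. With uniform
#' `alpha` this is the plain prototype: the unweighted mean of per-subject
#' class means.
#'
#' @param class_means array `(n_subjects, 2, 1024)`; `class_means[i, k + 1, ]`
#'   is subject `i`'s mean feature for class `k`.
#' @param alpha subject weights (length `n_subjects`, nonnegative, sum 1).
#' @return list with vectors `p0` and `p1` (each length 1024).
#' @export
compute_prototypes <- function(class_means, alpha) {
  d <- dim(class_means)
  if (is.null(d) || length(d) != 3L || d[2L] != 2L)
    stop_shape("class_means must be an (n_subjects, 2, dim) array")
  if (length(alpha) != d[1L])
    stop_shape("alpha length ", length(alpha), " != n_subjects ", d[1L])
  if (abs(sum(alpha) - 1) > 1e-6 || any(alpha < 0))
    stop_validation("alpha must be nonnegative and sum to 1")
  m0 <- matrix(class_means[, 1L, ], nrow = d[1L])
  m1 <- matrix(class_means[, 2L, ], nrow = d[1L])
  list(p0 = colSums(m0 * alpha), p1 = colSums(m1 * alpha))
}

#' Feature-level attention scores for both classes
#'
#' A small trainable net turns each class's mean support feature into a
#' per-dimension score vector: a 1-d convolution over the 1024-long class
#' mean (kernel `fa_w`, bias `fa_b`, zero padding), ReLU, softmax over the
#' 1024 dimensions, scaled by 1024 so `mean(z_k) = 1`. Zeroed net weights
#' give uniform logits, hence `z = 1` everywhere, and the weighted distance
#' degenerates to squared Euclidean distance -- the same reduction used when
#' `enabled = FALSE`.
#'
#' @param class_mean_0,class_mean_1 length-1024 mean support features of
#'   class 0 (nontarget) and class 1 (target).
#' @param fa_w convolution kernel (odd length), `NULL` when disabled.
#' @param fa_b scalar bias.
#' @param enabled logical; `FALSE` returns all-ones scores.
#' @return list with vectors `z0`, `z1` (length 1024, nonnegative, mean 1).
#' @export
feature_attention <- function(class_mean_0, class_mean_1, fa_w, fa_b = 0,
                              enabled = TRUE) {
  if (is.null(class_mean_0) || is.null(class_mean_1))
    stop_validation("both classes must be represented in the support set")
  n <- length(class_mean_0)
  if (!enabled) return(list(z0 = rep(1, n), z1 = rep(1, n)))
  one <- function(v) {
    logits <- pmax(conv1d_same(v, fa_w) + fa_b, 0)   # ReLU
    length(v) * softmax(logits)
  }
  list(z0 = one(class_mean_0), z1 = one(class_mean_1))
}

# 1-d convolution with zero padding ("same" output length); kernel length odd.
conv1d_same <- function(x, w) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  xp <- c(numeric(half), x, numeric(half))
  out <- numeric(length(x))
  for (j in seq_len(k)) out <- out + w[j] * xp[j:(j + length(x) - 1L)]
  out
}

#' Feature-attention-weighted squared distance
#'
#' `d(f, p_k) = sum_j z_k[j] * (f[j] - p_k[j])^2`. With `z = 1` this is the
#' squared Euclidean distance.
#'
#' @param f,p_k numeric vectors of equal length.
#' @param z_k nonnegative weight vector of the same length.
#' @return scalar `>= 0`.
#' @export
weighted_distance <- function(f, p_k, z_k) {
  if (length(f) != length(p_k) || length(f) != length(z_k))
    stop_shape("f, p_k and z_k must have equal length")
  if (any(z_k < 0)) stop_validation("z_k must be nonnegative")
  sum(z_k * (f - p_k)^2)
}

#' Class probabilities from the two prototype distances
#'
#' Negative-distance softmax: `P(y = k) = exp(-d_k) / (exp(-d0) + exp(-d1))`,
#' guarded against overflow by max-subtraction, so the nearer prototype gets
#' the larger probability and the two probabilities sum to 1.
#'
#' @param d0,d1 nonnegative distances to the nontarget / target prototype.
#'   Vectors are handled elementwise.
#' @return matrix with columns `p0`, `p1`.
#' @export
class_probabilities <- function(d0, d1) {
  s <- pmin(d0, d1)
  e0 <- exp(-(d0 - s)); e1 <- exp(-(d1 - s))
  tot <- e0 + e1
  cbind(p0 = e0 / tot, p1 = e1 / tot)
}

#' Mean binary cross-entropy classification loss
#'
#' Probabilities are clipped at `1e-12` before the log for numerical safety.
#'
#' @param probs matrix from [class_probabilities()] (columns `p0`, `p1`) or a
#'   vector of `P(y = 1)`.
#' @param labels binary vector (1 = target).
#' @return scalar loss `>= 0`.
#' @export
classification_loss <- function(probs, labels) {
  p1 <- if (is.matrix(probs)) probs[, "p1"] else probs
  if (length(p1) != length(labels))
    stop_shape("probs has ", length(p1), " rows but labels has length ", length(labels))
  p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  -mean(labels * log(p1) + (1 - labels) * log(1 - p1))
}

#' Prototype metric loss
#'
#' Mean over samples of (distance to the true-class prototype) minus
#' (distance to the other-class prototype): within-class distance enters
#' positively, between-class distance negatively, so minimizing pulls samples
#' toward their own prototype and pushes them from the other.
#'
#' @param distances_same,distances_other equal-length numeric vectors.
#' @return scalar (can be negative).
#' @export
metric_loss <- function(distances_same, distances_other) {
  if (length(distances_same) != length(distances_other))
    stop_shape("distance vectors must have equal length")
  mean(distances_same - distances_other)
}

#' Combine classification and metric loss
#'
#' `total = class_loss + lambda_metric * metric_loss`. The weighted sum keeps
#' the objective monotone in both terms; `lambda_metric` defaults to 1.
#'
#' @param class_loss,metric_loss scalars.
#' @param lambda_metric nonnegative weight of the metric term.
#' @return list with `class_loss`, `metric_loss`, `total`.
#' @export
total_loss <- function(class_loss, metric_loss, lambda_metric = 1.0) {
  if (lambda_metric < 0) stop_validation("lambda_metric must be >= 0")
  list(class_loss = class_loss, metric_loss = metric_loss,
       total = class_loss + lambda_metric * metric_loss)
}

#' Nearest-prototype classification of query features
#'
#' Each query row is assigned to the class whose feature-attention-weighted
#' prototype distance is smaller; exact ties break toward class 0
#' (nontarget). Probabilities come from [class_probabilities()].
#'
#' @param query_features matrix `(n x 1024)`.
#' @param prototypes list with `p0`, `p1` (from [compute_prototypes()]), or a
#'   list of per-row prototype lists when subject attention makes prototypes
#'   query-specific.
#' @param z list with `z0`, `z1` feature weights (default all ones).
#' @return list with integer vector `labels`, matrix `probs`, and matrix
#'   `distances` (columns `d0`, `d1`).
#' @export
classify <- function(query_features, prototypes, z = NULL) {
  query_features <- as.matrix(query_features)
  n <- nrow(query_features)
  if (is.null(z)) z <- list(z0 = rep(1, ncol(query_features)),
                            z1 = rep(1, ncol(query_features)))
  per_row <- is.null(prototypes$p0)
  d0 <- numeric(n); d1 <- numeric(n)
  for (i in seq_len(n)) {
    p <- if (per_row) prototypes[[i]] else prototypes
    d0[i] <- weighted_distance(query_features[i, ], p$p0, z$z0)
    d1[i] <- weighted_distance(query_features[i, ], p$p1, z$z1)
  }
  probs <- class_probabilities(d0, d1)
  labels <- as.integer(d1 < d0)   # tie (d1 == d0) -> 0
  list(labels = labels, probs = probs, distances = cbind(d0 = d0, d1 = d1))
}
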