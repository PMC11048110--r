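# Episodic meta-training: every training subject serves as the query subject
# once per epoch while the remaining subjects form the support set; Adam
# with cosine-annealed learning rate; all gradients (encoder and attention
# head) are analytic and verified against finite differences in the tests.

#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' learning rate `1e-4` and first-moment decay 0.9, query batches of 12
#' trials, cosine annealing of the learning rate to `lr / 100` over the full
#' run, and an equal weighting (`lambda_metric = 1`) of classification and
#' metric loss. `support_cap` bounds how many trials per support subject an
#' episode encodes (class-stratified sample); prototypes are class means, so
#' a balanced few-dozen-trial sample estimates them accurately at a fraction
#' of the cost of encoding every trial.
#'
#' @param epochs training epochs (each epoch = one episode per subject).
#' @param query_size query trials per episode (class-stratified,
#'   at least 1 target).
#' @param lr Adam learning rate.
#' @param optimizer only `"adam"` is implemented.
#' @param beta1,beta2 Adam moment decays.
#' @param scheduler cosine-annealing on/off.
#' @param lambda_metric weight of the metric loss term.
#' @param support_cap per-subject, per-episode cap on encoded support trials.
#' @param seed root seed for episode sampling, dropout and initialization
#'   downstream of [fit()].
#' @param device `"cpu"` (the only backend).
#' @return a validated `train_config` list.
#' @export
train_config <- function(epochs = 30, query_size = 12, lr = 1e-4,
                         optimizer = "adam", beta1 = 0.9, beta2 = 0.999,
                         scheduler = TRUE, lambda_metric = 1.0,
                         support_cap = 24, seed = 1, device = "cpu") {
  cfg <- as.list(environment())
  class(cfg) <- "train_config"
  validate_train_config(cfg)
}

validate_train_config <- function(cfg) {
  if (!is_count(cfg$epochs) || cfg$epochs < 0) stop_validation("epochs must be >= 0")
  if (!is_count(cfg$query_size) || cfg$query_size < 1) stop_validation("query_size must be >= 1")
  if (!is_scalar_num(cfg$lr) || cfg$lr <= 0) stop_validation("lr must be > 0")
  if (!identical(cfg$optimizer, "adam")) stop_validation("optimizer must be 'adam'")
  if (!is_scalar_num(cfg$lambda_metric) || cfg$lambda_metric < 0)
    stop_validation("lambda_metric must be >= 0")
  if (!is_count(cfg$support_cap) || cfg$support_cap < 2)
    stop_validation("support_cap must be >= 2")
  if (!is_count(cfg$seed)) stop_validation("seed must be an integer")
  cfg
}

#' Episode plan for one training epoch
#'
#' One episode per training subject: each subject serves as the query
#' subject exactly once per epoch (in an order shuffled by the current RNG
#' state), with the remaining subjects as support. Query trials are a
#' class-stratified sample of `query_size` trials containing at least one
#' target.
#'
#' @param coll training `subject_collection` (`>= 2` subjects).
#' @param epoch_index 1-based epoch number (recorded in the specs).
#' @param config a [train_config()].
#' @return list of episode specs: `query_subject`, `support_subjects`,
#'   `query_trial_indices`, `epoch`.
#' @export
make_episodes <- function(coll, epoch_index, config) {
  config <- validate_train_config(config)
  ids <- subject_ids(coll)
  if (length(ids) < 2L) stop_validation("episodic training needs >= 2 subjects")
  order <- sample(ids)
  lapply(order, function(q) {
    labels <- coll[[q]]$labels
    tgt <- which(labels == 1L); non <- which(labels == 0L)
    if (length(tgt) == 0L)
      stop_validation("subject ", q, " has no target trials")
    n_t <- max(1L, min(length(tgt), round(config$query_size * length(tgt) / length(labels))))
    n_n <- min(length(non), config$query_size - n_t)
    idx <- c(resample(tgt, n_t), resample(non, n_n))
    list(query_subject = q,
         support_subjects = setdiff(ids, q),
         query_trial_indices = idx[sample.int(length(idx))],
         epoch = epoch_index)
  })
}

# sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

# Class-stratified support subsample for one subject: all targets up to
# cap/2, remainder filled with nontargets (and vice versa when targets
# dominate).
support_indices <- function(labels, cap) {
  tgt <- which(labels == 1L); non <- which(labels == 0L)
  if (length(tgt) + length(non) <= cap) return(seq_along(labels))
  n_t <- min(length(tgt), max(1L, cap %/% 2L))
  n_n <- min(length(non), cap - n_t)
  n_t <- min(length(tgt), cap - n_n)   # refill if nontargets were scarce
  sort(c(resample(tgt, n_t), resample(non, n_n)))
}

# --- the prototype head: forward pass, losses, and analytic gradients ----
#
# Inputs: support features fs (Ns x dim) with subject index si and class ci
# per row; query features fq (Q x dim) with labels yq. Returns the loss
# breakdown plus gradients wrt fs, fq, G, fa_w, fa_b.
proto_head <- function(model, fs, si, ci, fq, yq, lambda_metric,
                       want_grads = TRUE) {
  dims <- ncol(fs)
  subj <- sort(unique(si))
  m <- length(subj)
  Q <- nrow(fq)
  # per-subject class means
  M0 <- matrix(0, m, dims); M1 <- matrix(0, m, dims)
  rows0 <- vector("list", m); rows1 <- vector("list", m)
  for (i in seq_len(m)) {
    rows0[[i]] <- which(si == subj[i] & ci == 0L)
    rows1[[i]] <- which(si == subj[i] & ci == 1L)
    if (length(rows0[[i]]) == 0L || length(rows1[[i]]) == 0L)
      stop_validation("support subject ", subj[i],
                      " lacks trials of one class in this episode")
    M0[i, ] <- colMeans(fs[rows0[[i]], , drop = FALSE])
    M1[i, ] <- colMeans(fs[rows1[[i]], , drop = FALSE])
  }
  U <- (M0 + M1) / 2
  c0 <- colMeans(M0); c1 <- colMeans(M1)

  # feature attention
  if (model$feature_attention) {
    fa_w <- model$proto$fa_w; fa_b <- model$proto$fa_b
    v0 <- conv1d_same(c0, fa_w) + fa_b; l0 <- pmax(v0, 0); s0 <- softmax(l0)
    v1 <- conv1d_same(c1, fa_w) + fa_b; l1 <- pmax(v1, 0); s1 <- softmax(l1)
    z0 <- dims * s0; z1 <- dims * s1
  } else {
    z0 <- rep(1, dims); z1 <- rep(1, dims)
  }

  # subject attention (per query sample)
  if (model$subject_attention && m > 1L) {
    G <- model$proto$G
    GU <- U %*% t(G)        # m x dim
    GQ <- fq %*% t(G)       # Q x dim
    TT <- array(0, c(Q, m, dims))
    E <- matrix(0, Q, m)
    for (i in seq_len(m)) {
      TT[, i, ] <- tanh(GQ * rep(GU[i, ], each = Q))
      E[, i] <- rowSums(matrix(TT[, i, ], nrow = Q))
    }
    A <- exp(E - apply(E, 1L, max)); A <- A / rowSums(A)
  } else {
    A <- matrix(1 / m, Q, m)
  }

  P0 <- A %*% M0            # Q x dim
  P1 <- A %*% M1
  R0 <- fq - P0; R1 <- fq - P1
  d0 <- as.vector(R0^2 %*% z0)
  d1 <- as.vector(R1^2 %*% z1)
  probs <- class_probabilities(d0, d1)
  cls <- classification_loss(probs, yq)
  ds <- ifelse(yq == 1L, d1, d0)
  dx <- ifelse(yq == 1L, d0, d1)
  met <- metric_loss(ds, dx)
  losses <- total_loss(cls, met, lambda_metric)
  out <- list(losses = losses, alpha = A, z = list(z0 = z0, z1 = z1),
              probs = probs, d0 = d0, d1 = d1, M0 = M0, M1 = M1)
  if (!want_grads) return(out)

  # --- backward ---
  p1v <- probs[, "p1"]
  # cross-entropy through the negative-distance softmax (s = d0 - d1)
  dsq <- (p1v - yq) / Q
  gd0 <- dsq + lambda_metric / Q * ifelse(yq == 1L, -1, 1)
  gd1 <- -dsq + lambda_metric / Q * ifelse(yq == 1L, 1, -1)

  dfq <- 2 * (R0 * gd0) * rep(z0, each = Q) + 2 * (R1 * gd1) * rep(z1, each = Q)
  dP0 <- -2 * (R0 * gd0) * rep(z0, each = Q)
  dP1 <- -2 * (R1 * gd1) * rep(z1, each = Q)
  dz0 <- as.vector(t(R0^2) %*% gd0)
  dz1 <- as.vector(t(R1^2) %*% gd1)

  dA <- dP0 %*% t(M0) + dP1 %*% t(M1)          # Q x m
  dM0 <- t(A) %*% dP0                          # m x dim
  dM1 <- t(A) %*% dP1

  dG <- NULL
  if (model$subject_attention && m > 1L) {
    dE <- A * (dA - rowSums(A * dA))           # softmax backward, per query row
    dGQ <- matrix(0, Q, dims)
    dGU <- matrix(0, m, dims)
    for (i in seq_len(m)) {
      pre <- dE[, i] * (1 - matrix(TT[, i, ], nrow = Q)^2)   # Q x dim
      dGQ <- dGQ + pre * rep(GU[i, ], each = Q)
      dGU[i, ] <- colSums(pre * GQ)
    }
    dG <- t(dGQ) %*% fq + t(dGU) %*% U
    dfq <- dfq + dGQ %*% G
    dU <- dGU %*% G
    dM0 <- dM0 + dU / 2
    dM1 <- dM1 + dU / 2
  }

  dfa_w <- NULL; dfa_b <- NULL
  if (model$feature_attention) {
    back_z <- function(dz, s, l, v, cm) {
      dl <- dims * s * (dz - sum(s * dz))
      dv <- dl * (v > 0)
      k <- length(fa_w); half <- (k - 1L) %/% 2L
      dw <- numeric(k)
      cp <- c(numeric(half), cm, numeric(half))
      for (j in seq_len(k)) dw[j] <- sum(dv * cp[j:(j + dims - 1L)])
      # transpose convolution back to the class mean
      dcp <- numeric(dims + 2L * half)
      for (j in seq_len(k)) {
        idx <- j:(j + dims - 1L)
        dcp[idx] <- dcp[idx] + fa_w[j] * dv
      }
      list(dw = dw, db = sum(dv), dc = dcp[(half + 1L):(half + dims)])
    }
    b0 <- back_z(dz0, s0, l0, v0, c0)
    b1 <- back_z(dz1, s1, l1, v1, c1)
    dfa_w <- b0$dw + b1$dw
    dfa_b <- b0$db + b1$db
    dM0 <- dM0 + rep(b0$dc / m, each = m)
    dM1 <- dM1 + rep(b1$dc / m, each = m)
  }

  dfs <- matrix(0, nrow(fs), dims)
  for (i in seq_len(m)) {
    dfs[rows0[[i]], ] <- rep(dM0[i, ] / length(rows0[[i]]), each = length(rows0[[i]]))
    dfs[rows1[[i]], ] <- rep(dM1[i, ] / length(rows1[[i]]), each = length(rows1[[i]]))
  }
  c(out, list(dfs = dfs, dfq = dfq, dG = dG, dfa_w = dfa_w, dfa_b = dfa_b))
}

# --- Adam over an arbitrary nested parameter list ---------------------------
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  # named lists are walked by name, unnamed ones (the per-branch kernel
  # list) positionally; a missing gradient leaves the leaf untouched
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      idx <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in idx) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

cosine_lr <- function(lr0, step, total_steps, enabled = TRUE, floor_frac = 0.01) {
  if (!enabled || total_steps <= 1) return(lr0)
  lr_floor <- lr0 * floor_frac
  lr_floor + 0.5 * (lr0 - lr_floor) * (1 + cos(pi * (step - 1) / (total_steps - 1)))
}

# Assemble a (trials, channels, samples) array from selected trials.
gather_trials <- function(coll, picks) {
  n <- sum(vapply(picks, length, integer(1)))
  ref <- coll[[1L]]$data
  arr <- array(0, c(n, dim(ref)[2L], dim(ref)[3L]))
  si <- integer(n); ci <- integer(n)
  at <- 0L
  for (id in names(picks)) {
    idx <- picks[[id]]
    if (length(idx) == 0L) next
    arr[at + seq_along(idx), , ] <- coll[[id]]$data[idx, , , drop = FALSE]
    si[at + seq_along(idx)] <- match(id, names(picks))
    ci[at + seq_along(idx)] <- coll[[id]]$labels[idx]
    at <- at + length(idx)
  }
  list(data = arr, si = si, ci = ci)
}

#' One episodic training step
#'
#' Encodes a class-stratified sample of every support subject's trials and
#' the episode's query batch (training-mode batch norm, separate batches so
#' prototypes are provably independent of query data), runs the prototype
#' head, backpropagates the total loss and applies one Adam update. The
#' returned losses are those of the forward pass, i.e. before the update.
#'
#' @param model a `pronet_model`.
#' @param episode one element of [make_episodes()].
#' @param data the training `subject_collection`.
#' @param config a [train_config()].
#' @param opt_state Adam state (from a previous call), or `NULL` to start.
#' @param lr learning rate for this step (default `config$lr`).
#' @return list with the updated `model`, `opt_state`, `losses`
#'   (class/metric/total), and diagnostic `alpha` (query x support weights)
#'   and `z` vectors of this episode.
#' @export
train_step <- function(model, episode, data, config, opt_state = NULL,
                       lr = config$lr) {
  support <- data[episode$support_subjects]
  picks <- lapply(unclass(support), function(es)
    support_indices(es$labels, config$support_cap))
  sup <- gather_trials(support, picks)
  qx <- data[[episode$query_subject]]$data[episode$query_trial_indices, , , drop = FALSE]
  yq <- data[[episode$query_subject]]$labels[episode$query_trial_indices]

  enc <- model$encoder
  fwd_s <- enc_run(enc, sup$data, training = TRUE, want_cache = TRUE,
                   dropout_seed = sample.int(.Machine$integer.max, 1L))
  enc$buffers[names(fwd_s$bn_updates)] <- fwd_s$bn_updates
  # the query batch is normalized in the SUPPORT batch's statistical frame:
  # prototypes stay provably independent of query data, and support and
  # query features live in one consistent space
  fwd_q <- enc_run(enc, qx, training = TRUE, want_cache = TRUE,
                   dropout_seed = sample.int(.Machine$integer.max, 1L),
                   fixed_stats = fwd_s$batch_stats)

  head <- proto_head(model, fwd_s$features, sup$si, sup$ci,
                     fwd_q$features, yq, config$lambda_metric)
  if (!all(is.finite(unlist(head$losses))))
    stop("non-finite loss in episode (query subject ", episode$query_subject,
         ", epoch ", episode$epoch, "): class_loss=", head$losses$class_loss,
         " metric_loss=", head$losses$metric_loss)

  g_s <- enc_grad(enc, fwd_s$cache, head$dfs)
  g_q <- enc_grad(enc, fwd_q$cache, head$dfq)
  enc_grads <- sum_grads(g_s, g_q)

  params <- list(enc = enc$params, proto = list())
  grads <- list(enc = enc_grads, proto = list())
  if (!is.null(head$dG)) { params$proto$G <- model$proto$G; grads$proto$G <- head$dG }
  if (!is.null(head$dfa_w)) {
    params$proto$fa_w <- model$proto$fa_w; grads$proto$fa_w <- head$dfa_w
    params$proto$fa_b <- model$proto$fa_b; grads$proto$fa_b <- head$dfa_b
  }
  if (is.null(opt_state)) opt_state <- adam_init(params)
  upd <- adam_step(params, grads, opt_state, lr, config$beta1, config$beta2)
  enc$params <- upd$params$enc
  model$encoder <- enc
  for (nm in names(upd$params$proto)) model$proto[[nm]] <- upd$params$proto[[nm]]

  list(model = model, opt_state = upd$state, losses = head$losses,
       alpha = head$alpha, z = head$z,
       class_means = list(m0 = head$M0, m1 = head$M1))
}

# Elementwise sum of two structurally identical gradient lists.
sum_grads <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- sum_grads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

#' Fit the model by episodic meta-training
#'
#' Runs `epochs` epochs of one episode per training subject (each subject
#' queried once per epoch), with cosine annealing of the learning rate from
#' `lr` to `lr / 100` across all steps. The held-out test subject is, by
#' construction, never seen here: `fit()` receives only training subjects.
#'
#' @param data training `subject_collection` (`>= 2` subjects).
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param feature_attention,subject_attention logical ablation flags.
#' @param encoder `"incepa"` or `"plain"`.
#' @param verbose print per-epoch median loss?
#' @return a `pronet_fit` list: `model` (trained), `log` (one row per
#'   episode: epoch, episode, query_subject, class_loss, metric_loss, total,
#'   lr, alpha_sum, z0_mean, z1_mean), and `config`.
#' @export
fit <- function(data, encoder_cfg = encoder_config(), train_cfg = train_config(),
                feature_attention = TRUE, subject_attention = TRUE,
                encoder = c("incepa", "plain"), verbose = FALSE) {
  encoder <- match.arg(encoder)
  train_cfg <- validate_train_config(train_cfg)
  ids <- subject_ids(data)
  if (length(ids) < 2L) stop_validation("fit needs >= 2 training subjects")
  d <- dim(data[[1L]]$data)
  model <- build_model(encoder_cfg, n_channels = d[2L], n_samples = d[3L],
                       sfreq = data[[1L]]$sfreq, seed = train_cfg$seed,
                       feature_attention = feature_attention,
                       subject_attention = subject_attention, encoder = encoder)
  m <- length(ids)
  total_steps <- train_cfg$epochs * m
  log <- vector("list", total_steps)
  opt_state <- NULL
  step <- 0L
  with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      episodes <- make_episodes(data, ep, train_cfg)
      for (e in episodes) {
        step <- step + 1L
        lr <- cosine_lr(train_cfg$lr, step, total_steps, train_cfg$scheduler)
        res <- train_step(model, e, data, train_cfg, opt_state, lr)
        model <- res$model
        opt_state <- res$opt_state
        log[[step]] <- data.frame(
          epoch = ep, episode = step, query_subject = e$query_subject,
          class_loss = res$losses$class_loss,
          metric_loss = res$losses$metric_loss,
          total = res$losses$total, lr = lr,
          alpha_sum = sum(res$alpha[1L, ]),
          z0_mean = mean(res$z$z0), z1_mean = mean(res$z$z1),
          z_min = min(res$z$z0, res$z$z1))
      }
      if (verbose) {
        tot <- vapply(log[(step - m + 1L):step], function(r) r$total, numeric(1))
        cat(sprintf("[fit] epoch %d/%d  median total loss %.4f  lr %.2e\n",
                    ep, train_cfg$epochs, stats::median(tot),
                    log[[step]]$lr))
      }
    }
  })
  log <- if (step > 0L) do.call(rbind, log[seq_len(step)]) else
    data.frame(epoch = integer(), episode = integer(), query_subject = character(),
               class_loss = numeric(), metric_loss = numeric(), total = numeric(),
               lr = numeric(), alpha_sum = numeric(), z0_mean = numeric(),
               z1_mean = numeric(), z_min = numeric())
  structure(list(model = model, log = log, config = train_cfg), class = "pronet_fit")
}

#' @export
print.pronet_fit <- function(x, ...) {
  cat(sprintf("<pronet_fit> %d episodes over %d epochs; final total loss %.4f\n",
              nrow(x$log), max(c(0L, x$log$epoch)),
              if (nrow(x$log)) x$log$total[nrow(x$log)] else NA_real_))
  print(x$model)
  invisible(x)
}
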