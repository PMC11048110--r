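# Finite-difference verification of every analytic gradient: the encoder's
# backward pass (including batch-statistics terms of batch norm, the
# squeeze-and-excitation and efficient-channel-attention gates) and the
# prototype head (attention maps, feature scores, losses).

test_that("encoder backward matches central finite differences", {
  enc <- fd_encoder(seed = 7, dropout = 0)
  X <- withr::with_seed(42, array(rnorm(6 * 4 * 32), c(6, 4, 32)))
  W <- withr::with_seed(43, matrix(rnorm(6 * 1024), 6, 1024))
  loss_of <- function(e) {
    o <- protoerp:::enc_run(e, X, training = TRUE, dropout_seed = 1)
    sum(o$features * W)
  }
  out <- protoerp:::enc_run(enc, X, training = TRUE, want_cache = TRUE,
                            dropout_seed = 1)
  g <- protoerp:::enc_grad(enc, out$cache, W)
  eps <- 1e-5
  bump <- function(e, name, branch, i, dlt) {
    if (is.null(branch)) e$params[[name]][i] <- e$params[[name]][i] + dlt
    else e$params[[name]][[branch]][i] <- e$params[[name]][[branch]][i] + dlt
    e
  }
  check <- function(name, branch = NULL) {
    p <- if (is.null(branch)) enc$params[[name]] else enc$params[[name]][[branch]]
    ga <- if (is.null(branch)) g[[name]] else g[[name]][[branch]]
    ga <- as.numeric(ga)
    idx <- withr::with_seed(length(p), sample(length(p), min(3, length(p))))
    for (i in idx) {
      num <- (loss_of(bump(enc, name, branch, i, eps)) -
              loss_of(bump(enc, name, branch, i, -eps))) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4,
                   label = sprintf("d%s[%d] analytic", name, i),
                   expected.label = "finite difference")
    }
  }
  for (nm in c("se_w1", "se_b1", "se_w2", "se_b2", "wsp", "bn1_gamma",
               "bn1_beta", "wdt", "eca_w", "bn2_gamma", "bn2_beta",
               "wd", "bn3_gamma", "bn3_beta"))
    check(nm)
  check("wt", 1)
  check("wt", 2)
})

test_that("frozen-statistics backward matches finite differences", {
  enc <- fd_encoder(seed = 17, dropout = 0)
  Xs <- withr::with_seed(44, array(rnorm(8 * 4 * 32), c(8, 4, 32)))
  Xq <- withr::with_seed(45, array(rnorm(3 * 4 * 32), c(3, 4, 32)))
  W <- withr::with_seed(46, matrix(rnorm(3 * 1024), 3, 1024))
  sup_stats <- protoerp:::enc_run(enc, Xs, training = TRUE)$batch_stats
  loss_of <- function(e) {
    o <- protoerp:::enc_run(e, Xq, training = TRUE, dropout_seed = 1,
                            fixed_stats = sup_stats)
    sum(o$features * W)
  }
  out <- protoerp:::enc_run(enc, Xq, training = TRUE, want_cache = TRUE,
                            dropout_seed = 1, fixed_stats = sup_stats)
  g <- protoerp:::enc_grad(enc, out$cache, W)
  eps <- 1e-5
  for (nm in c("wsp", "wd", "bn3_gamma", "wdt")) {
    p <- enc$params[[nm]]
    idx <- withr::with_seed(length(p) + 1, sample(length(p), 3))
    for (i in idx) {
      e2 <- enc; e2$params[[nm]][i] <- e2$params[[nm]][i] + eps
      e3 <- enc; e3$params[[nm]][i] <- e3$params[[nm]][i] - eps
      num <- (loss_of(e2) - loss_of(e3)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]])[i], num, tolerance = 1e-4,
                   label = sprintf("frozen d%s[%d]", nm, i))
    }
  }
})

test_that("prototype head gradients match finite differences", {
  dims <- 1024
  m <- 3; per <- 8; Q <- 5
  fs <- random_features(m * per, seed = 21) * 0.5
  si <- rep(1:m, each = per)
  ci <- rep(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), m)
  fq <- random_features(Q, seed = 22) * 0.5
  yq <- c(1L, 0L, 0L, 1L, 0L)
  model <- list(
    proto = withr::with_seed(23, list(
      G = matrix(rnorm(dims * dims, sd = 0.5 / sqrt(dims)), dims, dims),
      fa_w = rnorm(9, sd = 0.3), fa_b = 0.05)),
    feature_attention = TRUE, subject_attention = TRUE)
  lam <- 0.7
  h <- protoerp:::proto_head(model, fs, si, ci, fq, yq, lam)
  loss_of <- function(model2, fs2 = fs, fq2 = fq)
    protoerp:::proto_head(model2, fs2, si, ci, fq2, yq, lam,
                          want_grads = FALSE)$losses$total
  eps <- 1e-6
  fd <- function(f_plus, f_minus) (f_plus - f_minus) / (2 * eps)

  idx <- withr::with_seed(24, sample(length(model$proto$G), 3))
  for (i in idx) {
    mp <- model; mp$proto$G[i] <- mp$proto$G[i] + eps
    mm <- model; mm$proto$G[i] <- mm$proto$G[i] - eps
    expect_equal(h$dG[i], fd(loss_of(mp), loss_of(mm)), tolerance = 1e-4)
  }
  for (i in c(1L, 5L, 9L)) {
    mp <- model; mp$proto$fa_w[i] <- mp$proto$fa_w[i] + eps
    mm <- model; mm$proto$fa_w[i] <- mm$proto$fa_w[i] - eps
    expect_equal(h$dfa_w[i], fd(loss_of(mp), loss_of(mm)), tolerance = 1e-4)
  }
  mp <- model; mp$proto$fa_b <- mp$proto$fa_b + eps
  mm <- model; mm$proto$fa_b <- mm$proto$fa_b - eps
  expect_equal(h$dfa_b, fd(loss_of(mp), loss_of(mm)), tolerance = 1e-4)

  idx <- withr::with_seed(25, sample(length(fs), 4))
  for (i in idx) {
    fp <- fs; fp[i] <- fp[i] + eps
    fm <- fs; fm[i] <- fm[i] - eps
    expect_equal(h$dfs[i], fd(loss_of(model, fs2 = fp), loss_of(model, fs2 = fm)),
                 tolerance = 1e-3)
  }
  idx <- withr::with_seed(26, sample(length(fq), 4))
  for (i in idx) {
    fp <- fq; fp[i] <- fp[i] + eps
    fm <- fq; fm[i] <- fm[i] - eps
    expect_equal(h$dfq[i], fd(loss_of(model, fq2 = fp), loss_of(model, fq2 = fm)),
                 tolerance = 1e-3)
  }
})
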