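# Encoder construction, determinism, batch-norm contract and
# permutation/duplication invariances.

test_that("configuration contracts are enforced at build time", {
  expect_error(encoder_config(eca_kernel = 4), "odd")
  expect_error(encoder_config(out_dim = 512), "1024")
  expect_error(encoder_config(dropout = 1), "dropout")
  cfg <- encoder_config()
  # 0.256 s at 250 Hz is a 65-tap kernel: longer than a 40-sample epoch
  expect_error(build_encoder(cfg, 8, 40, 250, 1), "exceeds the epoch")
  expect_error(build_encoder(encoder_config(sep_kernel = 20), 8, 64, 64, 1),
               "sep_kernel")
  expect_error(build_encoder(encoder_config(pool1 = 64, pool2 = 8), 8, 64, 64, 1),
               "zero")
})

test_that("builds are deterministic in the seed and report parameter counts", {
  a <- build_encoder(encoder_config(), 8, 64, 64, seed = 5)
  b <- build_encoder(encoder_config(), 8, 64, 64, seed = 5)
  expect_identical(a$params, b$params)
  d <- build_encoder(encoder_config(), 8, 64, 64, seed = 6)
  expect_false(identical(a$params$wd, d$params$wd))
  expect_gt(a$n_params, 0)
  expect_identical(a$taps, c(17L, 9L, 5L))     # odd-rounded 0.256/0.128/0.064 s at 64 Hz
})

test_that("features are n x 1024 with near-zero training-mode column means", {
  enc <- build_encoder(encoder_config(), 8, 64, 64, seed = 2)
  es <- withr::with_seed(3, epoch_set(array(rnorm(128 * 8 * 64), c(128, 8, 64)),
                                      rep(c(0, 1), 64), "X", 64, paste0("c", 1:8)))
  fb <- withr::with_seed(4, encode(enc, es, training_mode = TRUE))
  expect_identical(dim(fb$features), c(128L, 1024L))
  expect_lt(max(abs(colMeans(fb$features))), 1e-3)
  expect_true(all(is.finite(fb$features)))
  expect_identical(fb$labels, es$labels)
})

test_that("evaluation-mode encoding is bit-deterministic", {
  enc <- build_encoder(encoder_config(), 8, 64, 64, seed = 2)
  es <- withr::with_seed(5, epoch_set(array(rnorm(10 * 8 * 64), c(10, 8, 64)),
                                      rep(0:1, 5), "X", 64, paste0("c", 1:8)))
  f1 <- encode(enc, es)$features
  f2 <- encode(enc, es)$features
  expect_identical(f1, f2)
  expect_error(encode(enc, withr::with_seed(1, epoch_set(
    array(rnorm(2 * 4 * 64), c(2, 4, 64)), 0:1, "Y", 64, paste0("c", 1:4)))),
    "expects")
})

test_that("trial permutation permutes feature rows identically", {
  enc <- fd_encoder(seed = 8)
  X <- withr::with_seed(6, array(rnorm(12 * 4 * 32), c(12, 4, 32)))
  perm <- withr::with_seed(7, sample(12))
  f <- protoerp:::enc_run(enc, X, training = TRUE, dropout_seed = 0)$features
  fp <- protoerp:::enc_run(enc, X[perm, , , drop = FALSE], training = TRUE,
                           dropout_seed = 0)$features
  expect_equal(fp, f[perm, ], tolerance = 1e-9)
})

test_that("duplicating every trial leaves training-mode features unchanged", {
  # batch statistics are invariant to duplicating the batch, so the
  # normalized features of the original trials must not move
  enc <- fd_encoder(seed = 9, dropout = 0)
  X <- withr::with_seed(8, array(rnorm(9 * 4 * 32), c(9, 4, 32)))
  Xdup <- X[rep(1:9, 2), , , drop = FALSE]
  f <- protoerp:::enc_run(enc, X, training = TRUE, dropout_seed = 0)$features
  fdup <- protoerp:::enc_run(enc, Xdup, training = TRUE, dropout_seed = 0)$features
  expect_equal(fdup[1:9, ], f, tolerance = 1e-9)
})

test_that("plain and attention-augmented variants differ only by the gates", {
  plain <- fd_encoder(seed = 10, variant = "plain")
  incepa <- fd_encoder(seed = 10, variant = "incepa")
  X <- withr::with_seed(9, array(rnorm(6 * 4 * 32), c(6, 4, 32)))
  fp <- protoerp:::enc_run(plain, X, training = FALSE)$features
  fi <- protoerp:::enc_run(incepa, X, training = FALSE)$features
  expect_false(isTRUE(all.equal(fp, fi)))
  expect_identical(dim(fp), dim(fi))
})

test_that("dropout masks are reproducible from the seed", {
  enc <- fd_encoder(seed = 11, dropout = 0.5)
  X <- withr::with_seed(10, array(rnorm(6 * 4 * 32), c(6, 4, 32)))
  f1 <- protoerp:::enc_run(enc, X, training = TRUE, dropout_seed = 99)$features
  f2 <- protoerp:::enc_run(enc, X, training = TRUE, dropout_seed = 99)$features
  f3 <- protoerp:::enc_run(enc, X, training = TRUE, dropout_seed = 100)$features
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("query batches can be normalized in a support batch's frame", {
  enc <- fd_encoder(seed = 12, dropout = 0)
  Xs <- withr::with_seed(11, array(rnorm(20 * 4 * 32), c(20, 4, 32)))
  Xq <- withr::with_seed(12, array(rnorm(3 * 4 * 32), c(3, 4, 32)))
  sup <- protoerp:::enc_run(enc, Xs, training = TRUE, dropout_seed = 0)
  q <- protoerp:::enc_run(enc, Xq, training = TRUE, dropout_seed = 0,
                          fixed_stats = sup$batch_stats)
  # a query trial equal to a support trial lands exactly on that support
  # trial's feature vector when both share the support statistics
  Xq2 <- Xs[1:2, , , drop = FALSE]
  q2 <- protoerp:::enc_run(enc, Xq2, training = TRUE, dropout_seed = 0,
                           fixed_stats = sup$batch_stats)
  expect_equal(q2$features, sup$features[1:2, ], tolerance = 1e-9)
  expect_identical(dim(q$features), c(3L, 1024L))
})
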