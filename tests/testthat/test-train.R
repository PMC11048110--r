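# Episodic training: episode bookkeeping, leakage guarantees, determinism,
# optimizer behavior and the learning curve on a small cohort.

test_that("each epoch queries every subject exactly once", {
  coll <- tiny_cohort(n_subjects = 5, trials = 50, seed = 1)
  cfg <- tiny_train_cfg()
  eps <- withr::with_seed(2, make_episodes(coll, 1, cfg))
  expect_length(eps, 5)
  qs <- vapply(eps, `[[`, character(1), "query_subject")
  expect_setequal(qs, subject_ids(coll))
  for (e in eps) {
    expect_false(e$query_subject %in% e$support_subjects)
    expect_setequal(c(e$query_subject, e$support_subjects), subject_ids(coll))
    expect_identical(anyDuplicated(e$query_trial_indices), 0L)
    expect_length(e$query_trial_indices, cfg$query_size)
    labels <- coll[[e$query_subject]]$labels[e$query_trial_indices]
    expect_gte(sum(labels), 1)               # class-stratified: >= 1 target
  }
  eps2 <- withr::with_seed(2, make_episodes(coll, 1, cfg))
  expect_identical(eps, eps2)                # seeded determinism
})

test_that("subjects without target trials are rejected", {
  coll <- tiny_cohort(n_subjects = 2, trials = 30, seed = 3)
  coll[[1]]$labels[] <- 0L
  expect_error(withr::with_seed(1, make_episodes(coll, 1, tiny_train_cfg())),
               "no target")
})

test_that("train_step reports pre-update losses and honors lambda", {
  coll <- tiny_cohort(n_subjects = 3, trials = 50, seed = 4)
  cfg <- tiny_train_cfg(lambda_metric = 0)
  d <- dim(coll[[1]]$data)
  model <- build_model(tiny_encoder_cfg(), d[2], d[3], coll[[1]]$sfreq, seed = 5)
  withr::with_seed(6, {
    ep <- make_episodes(coll, 1, cfg)[[1]]
    res <- train_step(model, ep, coll, cfg)
    expect_identical(res$losses$total, res$losses$class_loss)
    expect_true(is.finite(res$losses$total))
    # one Adam step actually moved the parameters
    expect_false(identical(res$model$encoder$params$wd, model$encoder$params$wd))
  })
})

test_that("episode prototypes are independent of the query subject's data", {
  coll <- tiny_cohort(n_subjects = 3, trials = 50, seed = 7)
  cfg <- tiny_train_cfg()
  d <- dim(coll[[1]]$data)
  model <- build_model(tiny_encoder_cfg(), d[2], d[3], coll[[1]]$sfreq, seed = 8)
  ep <- withr::with_seed(9, make_episodes(coll, 1, cfg))[[1]]
  res1 <- withr::with_seed(10, train_step(model, ep, coll, cfg))
  zeroed <- coll
  zeroed[[ep$query_subject]]$data[] <- 0
  res2 <- withr::with_seed(10, train_step(model, ep, zeroed, cfg))
  expect_identical(res2$class_means, res1$class_means)
})

test_that("cross-entropy in the loss log matches independent recomputation", {
  coll <- tiny_cohort(n_subjects = 3, trials = 50, seed = 11)
  d <- dim(coll[[1]]$data)
  model <- build_model(tiny_encoder_cfg(), d[2], d[3], coll[[1]]$sfreq, seed = 12)
  cfg <- tiny_train_cfg(lambda_metric = 0)
  withr::with_seed(13, {
    ep <- make_episodes(coll, 1, cfg)[[1]]
    # reproduce the forward pass by hand via the head on the same features
    sup_ids <- ep$support_subjects
    picks <- lapply(unclass(coll[sup_ids]), function(es)
      protoerp:::support_indices(es$labels, cfg$support_cap))
    sup <- protoerp:::gather_trials(coll[sup_ids], picks)
    fs <- protoerp:::enc_run(model$encoder, sup$data, TRUE, dropout_seed = 1)
    fq <- protoerp:::enc_run(model$encoder,
      coll[[ep$query_subject]]$data[ep$query_trial_indices, , , drop = FALSE],
      TRUE, dropout_seed = 2, fixed_stats = fs$batch_stats)
    yq <- coll[[ep$query_subject]]$labels[ep$query_trial_indices]
    h <- protoerp:::proto_head(model, fs$features, sup$si, sup$ci,
                               fq$features, yq, 0, want_grads = FALSE)
    # independent oracle: probabilities from the distances, then mean BCE
    p1 <- exp(-(h$d1 - pmin(h$d0, h$d1))) /
          (exp(-(h$d0 - pmin(h$d0, h$d1))) + exp(-(h$d1 - pmin(h$d0, h$d1))))
    p1c <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
    ce <- -mean(yq * log(p1c) + (1 - yq) * log(1 - p1c))
    expect_equal(h$losses$class_loss, ce, tolerance = 1e-12)
    expect_identical(h$losses$total, h$losses$class_loss)
  })
})

test_that("fit is reproducible, logs every episode, and respects epochs = 0", {
  coll <- tiny_cohort(n_subjects = 3, trials = 50, seed = 14)
  cfg <- tiny_train_cfg(epochs = 2, seed = 99)
  f1 <- fit(coll, encoder_cfg = tiny_encoder_cfg(), train_cfg = cfg)
  f2 <- fit(coll, encoder_cfg = tiny_encoder_cfg(), train_cfg = cfg)
  expect_identical(f1$log$total, f2$log$total)
  expect_identical(f1$model$encoder$params, f2$model$encoder$params)
  expect_identical(nrow(f1$log), 2L * 3L)
  expect_identical(f1$log$epoch, rep(1:2, each = 3))

  f0 <- fit(coll, encoder_cfg = tiny_encoder_cfg(),
            train_cfg = tiny_train_cfg(epochs = 0, seed = 99))
  init <- build_model(tiny_encoder_cfg(), 8, 64, 64, seed = 99)
  expect_identical(f0$model$encoder$params, init$encoder$params)
  expect_identical(nrow(f0$log), 0L)
})

test_that("the cosine schedule anneals from lr to lr/100", {
  lrs <- vapply(1:10, function(s) protoerp:::cosine_lr(1e-3, s, 10), numeric(1))
  expect_equal(lrs[1], 1e-3, tolerance = 1e-12)
  expect_equal(lrs[10], 1e-5, tolerance = 1e-12)
  expect_true(all(diff(lrs) < 0))
  expect_identical(protoerp:::cosine_lr(1e-3, 5, 10, enabled = FALSE), 1e-3)
})

test_that("training reduces the loss on an easy cohort", {
  # strong ERP (amplitude 4x the driving noise) so the learning signal is
  # visible within a short run
  coll <- tiny_cohort(n_subjects = 4, trials = 80, seed = 15, ratio_amp = 4)
  ok <- 0
  for (seed in 1:3) {
    f <- fit(coll, encoder_cfg = tiny_encoder_cfg(),
             train_cfg = tiny_train_cfg(epochs = 10, seed = seed))
    agg <- stats::aggregate(total ~ epoch, f$log, stats::median)
    if (agg$total[nrow(agg)] < agg$total[1]) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("the Adam walker updates every leaf it has gradients for", {
  params <- list(a = matrix(1, 2, 2), nested = list(b = rep(0.5, 3)))
  grads <- list(a = matrix(1, 2, 2), nested = list(b = rep(-1, 3)))
  st <- protoerp:::adam_init(params)
  up <- protoerp:::adam_step(params, grads, st, lr = 0.1, beta1 = 0.9,
                             beta2 = 0.999)
  expect_true(all(up$params$a < params$a))
  expect_true(all(up$params$nested$b > params$nested$b))
  expect_identical(up$state$t, 1L)
  # missing gradient leaves the leaf untouched
  up2 <- protoerp:::adam_step(params, list(a = grads$a), st, 0.1, 0.9, 0.999)
  expect_identical(up2$params$nested$b, params$nested$b)
})
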