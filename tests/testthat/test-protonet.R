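# Prototype-network core operations against closed-form and brute-force
# oracles, plus the attention-reduction invariants.

test_that("weighted distance matches elementwise arithmetic oracles", {
  n <- 1024
  f <- numeric(n); p <- numeric(n); z <- rep(1, n)
  expect_identical(weighted_distance(f, f, z), 0)
  f2 <- numeric(n); f2[1:2] <- c(3, 4)
  expect_equal(weighted_distance(f2, p, z), 25, tolerance = 1e-9)
  z2 <- c(2, 0.5, numeric(n - 2)); f3 <- c(1, 2, numeric(n - 2))
  expect_equal(weighted_distance(f3, p, z2), 4, tolerance = 1e-9)
  expect_error(weighted_distance(f3, p, -z), "nonnegative")
  expect_error(weighted_distance(f3, p[1:3], z), "equal length")
})

test_that("class probabilities follow the negative-distance softmax", {
  expect_equal(unname(class_probabilities(1, 1)), matrix(c(0.5, 0.5), 1),
               tolerance = 1e-12)
  expect_equal(class_probabilities(0, log(3))[, "p0"], c(p0 = 0.75),
               tolerance = 1e-9)
  withr::with_seed(4, {
    d0 <- runif(50, 0, 2000); d1 <- runif(50, 0, 2000)
    p <- class_probabilities(d0, d1)
    expect_equal(unname(rowSums(p)), rep(1, 50), tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    # nearer prototype always gets the larger probability
    expect_identical(unname(p[, "p1"] > 0.5), unname(d1 < d0))
  })
})

test_that("classification loss is the clipped mean binary cross-entropy", {
  expect_lt(classification_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(classification_loss(rep(0.5, 8), rep(c(0, 1), 4)), log(2),
               tolerance = 1e-9)
  withr::with_seed(1, {
    p <- runif(20); y <- rbinom(20, 1, 0.5)
    o <- sample(20)
    expect_equal(classification_loss(p, y), classification_loss(p[o], y[o]),
                 tolerance = 1e-12)
  })
  expect_true(is.finite(classification_loss(c(0, 1), c(1, 0))))
})

test_that("metric loss is the mean within-minus-between distance", {
  expect_identical(metric_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(metric_loss(c(1, 2), c(3, 4)), -2, tolerance = 1e-9)
  expect_lt(metric_loss(c(0.5, 2), c(3, 4)), metric_loss(c(1, 2), c(3, 4)))
})

test_that("total loss combines terms linearly", {
  expect_identical(total_loss(0.7, -0.3, 0)$total, 0.7)
  expect_equal(total_loss(0.7, -0.3, 1.0)$total, 0.4, tolerance = 1e-12)
  t1 <- total_loss(0.5, 1, 2)$total
  t2 <- total_loss(0.5, 2, 2)$total
  expect_equal(t2 - t1, 2, tolerance = 1e-12)
  expect_error(total_loss(1, 1, -1), "lambda")
})

test_that("softmax of subject scores matches scalar arithmetic", {
  expect_equal(protoerp:::softmax(c(log(2), 0)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(protoerp:::softmax(rep(3, 5)), rep(0.2, 5), tolerance = 1e-12)
})

test_that("subject attention reduces to uniform weights when disabled", {
  u <- random_features(5, seed = 2)
  q <- random_features(1, seed = 3)[1, ]
  expect_identical(subject_attention(u, q, NULL, enabled = FALSE), rep(0.2, 5))
  g <- diag(1024)
  a <- subject_attention(u, q, g, enabled = TRUE)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(all(a >= 0))
  # identical support subjects get identical weights
  u2 <- u[c(1, 1, 1), ]
  expect_equal(subject_attention(u2, q, g), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(subject_attention(u, q[1:10], g), "match")
})

test_that("prototypes are alpha-weighted means of subject class means", {
  cm <- array(0, c(2, 2, 1024))
  cm[1, 1, ] <- 1; cm[1, 2, ] <- 2
  cm[2, 1, ] <- 0; cm[2, 2, ] <- 1
  # single support subject: its class means verbatim
  one <- compute_prototypes(cm[1, , , drop = FALSE], 1)
  expect_identical(one$p0, rep(1, 1024))
  expect_identical(one$p1, rep(2, 1024))
  # uniform alpha: the plain unweighted mean
  uni <- compute_prototypes(cm, c(0.5, 0.5))
  expect_equal(uni$p0, rep(0.5, 1024), tolerance = 1e-12)
  expect_equal(uni$p1, rep(1.5, 1024), tolerance = 1e-12)
  # weighted-mean arithmetic
  w <- compute_prototypes(cm, c(0.8, 0.2))
  expect_equal(w$p0, rep(0.8, 1024), tolerance = 1e-9)
  expect_error(compute_prototypes(cm, c(0.7, 0.7)), "sum to 1")
  expect_error(compute_prototypes(cm, 1), "length")
})

test_that("feature attention scores are nonnegative with mean one", {
  c0 <- random_features(1, seed = 5)[1, ]
  c1 <- random_features(1, seed = 6)[1, ]
  off <- feature_attention(c0, c1, NULL, enabled = FALSE)
  expect_identical(off$z0, rep(1, 1024))
  # zeroed net weights give exactly uniform scores
  z <- feature_attention(c0, c1, numeric(9), 0)
  expect_equal(z$z0, rep(1, 1024), tolerance = 1e-12)
  expect_equal(z$z1, rep(1, 1024), tolerance = 1e-12)
  withr::with_seed(8, {
    w <- rnorm(9, sd = 0.5)
    z2 <- feature_attention(c0, c1, w, 0.1)
    expect_equal(mean(z2$z0), 1, tolerance = 1e-6)
    expect_equal(mean(z2$z1), 1, tolerance = 1e-6)
    expect_true(all(z2$z0 >= 0) && all(z2$z1 >= 0))
  })
})

test_that("classification matches a brute-force nearest-prototype oracle", {
  # hand-placed prototypes and queries in a 2-d subspace of feature space
  p0 <- numeric(1024); p1 <- numeric(1024)
  p0[1:2] <- c(0, 0); p1[1:2] <- c(2, 2)
  qs <- rbind(c(0.1, 0), c(1.9, 2), c(1, 1), c(3, 3), c(-1, 2), c(2, 0),
              c(0.9, 1.2), c(1.2, 0.9))
  query <- matrix(0, nrow(qs), 1024); query[, 1:2] <- qs
  res <- classify(query, list(p0 = p0, p1 = p1))
  oracle <- apply(qs, 1, function(q) {
    d <- c(sum(q^2), sum((q - c(2, 2))^2))
    which.min(d) - 1L                       # which.min takes the first: tie -> 0
  })
  expect_identical(res$labels, as.integer(oracle))
  # exact tie breaks toward nontarget
  tie <- matrix(0, 1, 1024); tie[1, 1:2] <- c(1, 1)
  expect_identical(classify(tie, list(p0 = p0, p1 = p1))$labels, 0L)
  # query at the target prototype
  at_p1 <- matrix(p1, 1)
  r <- classify(at_p1, list(p0 = p0, p1 = p1))
  expect_identical(r$labels, 1L)
  expect_gt(r$probs[, "p1"], 0.5)
})

test_that("disabled feature attention makes the distance exactly Euclidean", {
  f <- random_features(6, seed = 9)
  p <- random_features(1, seed = 10)[1, ]
  z <- feature_attention(p, p, NULL, enabled = FALSE)
  for (i in 1:6)
    expect_identical(weighted_distance(f[i, ], p, z$z0), sum((f[i, ] - p)^2))
})

test_that("classification is invariant to common positive rescaling of z", {
  # small-magnitude features keep the probability map away from saturation,
  # so score orderings are strict
  f <- random_features(10, seed = 11) * 0.03
  p0 <- random_features(1, seed = 12)[1, ] * 0.03
  p1 <- random_features(1, seed = 13)[1, ] * 0.03
  z <- abs(random_features(1, seed = 14)[1, ]) + 0.1
  a <- classify(f, list(p0 = p0, p1 = p1), list(z0 = z, z1 = z))
  b <- classify(f, list(p0 = p0, p1 = p1), list(z0 = 7 * z, z1 = 7 * z))
  expect_identical(a$labels, b$labels)
  expect_identical(order(a$probs[, "p1"]), order(b$probs[, "p1"]))
})
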