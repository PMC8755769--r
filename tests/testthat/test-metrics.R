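test_that("validity reproduces hand-computed examples", {
  expect_equal(validity(c(1, 2, 1), c(1, 2, 1), "categorical"), 1)
  expect_equal(validity(rep(25, 4), rep(20, 4), "continuous"), 0.25)
  expect_equal(validity(c(rep("a", 7), rep("b", 3)), rep("a", 10), "categorical"), 0.7)
  expect_error(validity(1:3, c(1, 0, 2), "continuous"), "zero")
  expect_error(validity(1:3, 1:2), "length")
})

test_that("confidence comes from softmax probabilities of the target class", {
  pl <- demo_pipeline32()
  z <- pl$Zh[1, ]
  p <- class_probabilities(pl$lbc, z)
  expect_equal(confidence(pl$lbc, z, "abnormal"), p[2], tolerance = 1e-12)
  expect_equal(confidence(pl$lbc, z, 1) + confidence(pl$lbc, z, 2), 1,
               tolerance = 1e-9)
  expect_error(confidence(pl$lbc, z, 5), "class")
  # extreme logits saturate to ~1
  expect_equal(drop(tracecf:::softmax(matrix(c(10, -10), 1)))[1], 1,
               tolerance = 1e-4)
})

test_that("sparsity counts altered pixels", {
  x <- matrix(0.5, 10, 10)
  expect_equal(sparsity(x, x), 0)
  xb <- x; xb[3, 7] <- 0.9
  expect_equal(sparsity(x, xb), 0.01)
  expect_equal(sparsity(x, x + 1), 1)
  expect_error(sparsity(x, matrix(0, 5, 5)), "shape")
})

test_that("proximity reproduces hand cases and the brute-force scan", {
  train <- rbind(c(1, 0), c(2, 0), c(5, 0))
  expect_equal(proximity(c(0, 0), train, K = 2), 1.5)
  expect_equal(proximity(train[1, ], train, K = 1), 0)
  expect_error(proximity(c(0, 0), train, K = 5), "K")
  set.seed(21)
  for (rep in 1:5) {
    tr <- matrix(rnorm(60 * 4), 60)
    zb <- rnorm(4)
    expect_equal(proximity(zb, tr, K = 5), proximity_oracle(zb, tr, 5),
                 tolerance = 1e-9)
  }
})

test_that("realism reproduces hand evaluations and decays off-manifold", {
  real <- matrix(c(0, 1), ncol = 1)
  expect_equal(realism(0.5, real, K = 1), 2)
  expect_equal(realism(10, real, K = 1), max(1 / 10, 1 / 9), tolerance = 1e-12)
  expect_lt(realism(10, real, K = 1), realism(0.5, real, K = 1))
  expect_equal(realism(1, real, K = 1), 1e6)  # coincidence sentinel
  expect_error(realism(0.5, real, K = 2), "K \\+ 1")
})

test_that("metric kernels match brute force on random small instances", {
  set.seed(14)
  for (rep in 1:25) {
    # validity
    n <- sample(3:12, 1)
    pred <- sample(1:3, n, replace = TRUE)
    targ <- sample(1:3, n, replace = TRUE)
    expect_equal(validity(pred, targ, "categorical"),
                 validity_oracle(pred, targ, "categorical"), tolerance = 1e-9)
    vc <- abs(rnorm(n)) + 0.5
    expect_equal(validity(pred, vc, "continuous"),
                 validity_oracle(pred, vc, "continuous"), tolerance = 1e-9)
    # sparsity
    h <- sample(4:8, 1)
    x <- matrix(runif(h * h), h); xb <- x + matrix(rnorm(h * h, sd = 0.01), h)
    expect_equal(sparsity(x, xb), sparsity_oracle(x, xb, 1 / 255), tolerance = 1e-9)
    # proximity
    tr <- matrix(rnorm(20 * 3), 20); zb <- rnorm(3)
    expect_equal(proximity(zb, tr, K = 4), proximity_oracle(zb, tr, 4),
                 tolerance = 1e-9)
    # realism
    real <- matrix(rnorm(12 * 3), 12); g <- rnorm(3)
    expect_equal(realism(g, real, K = 3), realism_oracle(g, real, 3),
                 tolerance = 1e-9)
  }
})

test_that("realism is invariant to a common rigid rotation of all features", {
  set.seed(15)
  real <- matrix(rnorm(20 * 2), 20)
  g <- rnorm(2)
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(realism(drop(R %*% g), real %*% t(R), K = 3),
               realism(g, real, K = 3), tolerance = 1e-9)
})

test_that("batch evaluation aggregates correctly", {
  pl <- demo_pipeline32()
  qix <- normal_queries(pl, 6)
  Zq <- encode(pl$wae, pl$ds$images[, , qix])
  res <- generate_trace(Zq, "abnormal", pl$lbc, pl$wae, cf_config(steps = 120))
  rep6 <- evaluate_batch(res, pl$ds$images[, , qix], rep("abnormal", 6),
                         pl$lbc, pl$wae, pl$ds$images[, , pl$train_ix])
  expect_s3_class(rep6, "metrics_report")
  expect_equal(rep6$N, 6)
  expect_true(all(rep6$rows$valid %in% 0:1))
  expect_true(all(rep6$rows$sparsity >= 0 & rep6$rows$sparsity <= 1))
  expect_true(all(rep6$rows$proximity >= 0))
  expect_true(all(rep6$rows$realism > 0))
  # aggregates equal an independent recomputation from the rows
  for (m in c("confidence", "sparsity", "proximity", "realism")) {
    expect_equal(rep6$aggregates$mean[rep6$aggregates$metric == m],
                 mean(rep6$rows[[m]]), tolerance = 1e-12)
    expect_equal(rep6$aggregates$sd[rep6$aggregates$metric == m],
                 sd(rep6$rows[[m]]), tolerance = 1e-12)
  }
  # single-row report: aggregates equal the row, sd 0
  rep1 <- evaluate_batch(res[[1]], pl$ds$images[, , qix[1], drop = FALSE],
                         "abnormal", pl$lbc, pl$wae,
                         pl$ds$images[, , pl$train_ix])
  expect_equal(rep1$aggregates$sd, rep(0, nrow(rep1$aggregates)))
  expect_equal(rep1$aggregates$mean[rep1$aggregates$metric == "sparsity"],
               rep1$rows$sparsity)
  # permutation invariance of the aggregates
  perm <- c(4, 2, 6, 1, 5, 3)
  repp <- evaluate_batch(res[perm], pl$ds$images[, , qix[perm]],
                         rep("abnormal", 6), pl$lbc, pl$wae,
                         pl$ds$images[, , pl$train_ix])
  expect_equal(repp$aggregates$mean, rep6$aggregates$mean, tolerance = 1e-9)
  expect_error(evaluate_batch(res, pl$ds$images[, , qix[1:3]],
                              rep("abnormal", 6), pl$lbc, pl$wae,
                              pl$ds$images[, , pl$train_ix]), "misaligned")
})
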