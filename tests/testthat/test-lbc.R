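test_that("label-to-logit encoding reproduces hand arithmetic", {
  l2 <- labels_to_logits(1, K = 2, eps_negative = 0.01)
  expect_equal(l2[1, ], c(log(99), -log(99)), tolerance = 1e-10)
  expect_equal(l2[1, 1], 4.5951, tolerance = 1e-4)

  l3 <- labels_to_logits(2, K = 3, eps_negative = 0.01)
  expect_equal(l3[1, 2], log(0.98 / 0.02), tolerance = 1e-10)
  expect_equal(l3[1, 2], 3.8918, tolerance = 1e-4)
  expect_equal(l3[1, c(1, 3)], rep(-log(99), 2), tolerance = 1e-10)

  # probabilities sum to one before the logit map, for any K
  for (K in 2:5) {
    lg <- labels_to_logits(1, K, 0.02)
    p <- 1 / (1 + exp(-lg))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(labels_to_logits(1, K = 2, eps_negative = 0.6), "eps_negative")
  expect_error(labels_to_logits(3, K = 2), "out of range")
})

test_that("interval calibration error reproduces hand-counted coverage", {
  # full coverage at alpha = 0.9
  expect_equal(interval_calibration_error(rep(0, 10), rep(100, 10),
                                          rnorm(10), 0.9), 0.1)
  # zero coverage
  expect_equal(interval_calibration_error(rep(0, 10), rep(0, 10),
                                          rep(1, 10), 0.9), 0.9)
  # exactly 9 of 10 covered
  y_hat <- rep(0, 10); delta <- rep(0.5, 10)
  y <- c(rep(0.2, 9), 5)
  expect_equal(interval_calibration_error(y_hat, delta, y, 0.9), 0)
  expect_error(interval_calibration_error(1:3, 1:3, 1:2, 0.9), "shape")
})

test_that("calibration error equals a brute-force loop over samples and outputs", {
  set.seed(12)
  N <- 40; K <- 3
  y_hat <- matrix(rnorm(N * K), N)
  delta <- matrix(abs(rnorm(N * K)), N)
  y <- matrix(rnorm(N * K), N)
  brute <- 0
  for (k in 1:K) {
    cov_k <- 0
    for (i in 1:N) {
      cov_k <- cov_k + as.numeric(y[i, k] >= y_hat[i, k] - delta[i, k] &&
                                    y[i, k] <= y_hat[i, k] + delta[i, k])
    }
    brute <- brute + abs(0.9 - cov_k / N)
  }
  expect_equal(interval_calibration_error(y_hat, delta, y, 0.9), brute,
               tolerance = 1e-12)
})

test_that("hinge interval loss reproduces hand-computed values", {
  expect_equal(hinge_interval_loss(0, 0.1, 1.0, 0.05), 0.95)
  expect_equal(hinge_interval_loss(1.0, 0.5, 1.2, 0.05), 0)
  expect_equal(hinge_interval_loss(0, 0.3, 0, 0), 0)    # centered target, tau 0
  # multi-output: sums over outputs, means over samples
  yh <- matrix(0, 2, 2); dl <- matrix(0.1, 2, 2)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(hinge_interval_loss(yh, dl, y, 0.05), 0.95)
})

test_that("hinge is zero iff targets lie in the margin-shrunk interval", {
  set.seed(13)
  for (rep in 1:20) {
    y_hat <- rnorm(5); delta <- abs(rnorm(5)) + 0.2; y <- rnorm(5)
    tau <- 0.05
    inside <- all(y >= y_hat - delta + tau & y <= y_hat + delta - tau)
    expect_identical(hinge_interval_loss(y_hat, delta, y, tau) == 0, inside)
  }
})

test_that("alternating training calibrates held-out coverage to alpha", {
  task <- synthetic_interval_regression(1800, seed = 4)
  tr <- 1:1200; te <- 1201:1800
  cfg <- lbc_config(f_hidden = c(64, 64), g_hidden = c(64, 64), epochs = 50)
  m <- train_lbc(task$z[tr, ], task$y[tr], "regression", cfg, seed = 4)
  cov <- tracecf:::interval_coverage(m, task$z[te, ], task$y[te])
  expect_gt(cov, 0.83)
  expect_lt(cov, 0.97)
  # intervals adapt to the heteroscedastic noise: wider where |z1| is large
  pr <- predict(m, task$z[te, ])
  hi <- abs(task$z[te, 1]) > 1
  expect_gt(mean(pr$delta[hi]), mean(pr$delta[!hi]))
})

test_that("lower alpha gives lower coverage and narrower intervals", {
  task <- synthetic_interval_regression(1500, seed = 9)
  tr <- 1:1000; te <- 1001:1500
  m9 <- train_lbc(task$z[tr, ], task$y[tr], "regression",
                  lbc_config(alpha = 0.9, f_hidden = c(64, 64),
                             g_hidden = c(64, 64), epochs = 40), seed = 2)
  m5 <- train_lbc(task$z[tr, ], task$y[tr], "regression",
                  lbc_config(alpha = 0.5, f_hidden = c(64, 64),
                             g_hidden = c(64, 64), epochs = 40), seed = 2)
  c9 <- tracecf:::interval_coverage(m9, task$z[te, ], task$y[te])
  c5 <- tracecf:::interval_coverage(m5, task$z[te, ], task$y[te])
  expect_lt(c5, c9)
  expect_lt(abs(c5 - 0.5), 0.12)
  expect_lt(mean(predict(m5, task$z[te, ])$delta),
            mean(predict(m9, task$z[te, ])$delta))
})

test_that("classification training separates well-separated latents", {
  set.seed(3)
  Z <- rbind(matrix(rnorm(400 * 5, -1), ncol = 5),
             matrix(rnorm(400 * 5, 1), ncol = 5))
  lab <- factor(rep(c("normal", "abnormal"), each = 400),
                levels = c("normal", "abnormal"))
  m <- train_lbc(Z, lab, "classification",
                 lbc_config(f_hidden = c(64, 64), g_hidden = c(64, 64),
                            epochs = 30), seed = 2)
  p <- class_probabilities(m, Z)
  expect_gt(mean((p[, 2] > 0.5) == (lab == "abnormal")), 0.9)
  expect_equal(rowSums(p), rep(1, 800), tolerance = 1e-6)
  pr <- predict(m, Z[1:5, ])
  expect_true(all(pr$delta >= 0))
})

test_that("prediction contracts hold and both coverage code paths agree", {
  pl <- demo_pipeline32()
  # equal logits give probability one half
  expect_equal(drop(tracecf:::softmax(matrix(c(1.3, 1.3), 1))), c(0.5, 0.5))
  # hard-indicator coverage computed via predict() equals interval_coverage
  pr <- predict(pl$lbc, pl$Zh)
  Y <- labels_to_logits(as.integer(pl$ds$labels[pl$holdout_ix]), 2, 0.01)
  manual <- mean(Y >= pr$y_hat - pr$delta & Y <= pr$y_hat + pr$delta)
  expect_equal(tracecf:::interval_coverage(pl$lbc, pl$Zh,
                                           pl$ds$labels[pl$holdout_ix]),
               manual, tolerance = 1e-12)
  # and the per-output coverages implied by the calibration error match too
  per_out <- colMeans(Y >= pr$y_hat - pr$delta & Y <= pr$y_hat + pr$delta)
  expect_equal(interval_calibration_error(pr$y_hat, pr$delta, Y, 0.9),
               sum(abs(0.9 - per_out)), tolerance = 1e-12)
  expect_error(predict(pl$lbc, matrix(0, 1, 7)), "dimension")
  expect_error(train_lbc(matrix(rnorm(20), 10), rep(1, 10), "classification"),
               "degenerate")
})
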