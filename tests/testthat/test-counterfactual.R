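test_that("the calibration objective reproduces term-by-term arithmetic", {
  pl <- demo_pipeline32()
  z <- pl$Zh[1, ]
  cfg <- cf_config(eta1 = 1, eta2 = 1, eta3 = 1, tau = 0.05)
  # brute-force evaluation from the model's own predictions
  oracle <- function(z_hat, z, model, k, cfg) {
    yh <- tracecf:::net_forward(model$F_net, matrix(z_hat, 1))$out
    dl <- tracecf:::net_forward(model$G_net, matrix(z_hat, 1))$out
    Y <- labels_to_logits(k, model$K, model$config$eps_negative)
    hinge <- 0
    for (j in seq_len(model$K)) {
      hinge <- hinge + max(0, (yh[j] - dl[j]) - Y[j] + cfg$tau) +
        max(0, Y[j] - (yh[j] + dl[j]) + cfg$tau)
    }
    cfg$eta1 * sum((z - z_hat)^2) + cfg$eta2 * hinge + cfg$eta3 * sum(dl)
  }
  set.seed(31)
  for (rep in 1:10) {
    zh <- z + rnorm(length(z), sd = 0.5)
    expect_equal(trace_cf_objective(zh, z, pl$lbc, "abnormal", cfg),
                 oracle(zh, z, pl$lbc, 2, cfg), tolerance = 1e-6)
  }
  # zero weights give zero objective
  cfg0 <- cf_config(eta1 = 0, eta2 = 0, eta3 = 0)
  expect_equal(trace_cf_objective(zh, z, pl$lbc, "abnormal", cfg0), 0)
})

test_that("hand-set example: eta (1,1,1), y_hat 0, delta 0.1, y_bar 1 gives 1.30", {
  # pure kernel arithmetic: proximity 0.25 + hinge 0.95 + width 0.1
  h <- hinge_interval_loss(0, 0.1, 1, 0.05)
  expect_equal(1 * 0.25 + 1 * h + 1 * 0.1, 1.30)
})

test_that("descent and determinism contracts hold for the trace generator", {
  pl <- demo_pipeline32()
  qix <- normal_queries(pl, 4)
  Zq <- encode(pl$wae, pl$ds$images[, , qix])
  cfg <- cf_config(steps = 120)
  res <- generate_trace(Zq, "abnormal", pl$lbc, pl$wae, cfg)
  for (r in res) {
    expect_lte(r$objective, r$trajectory$objective[1] + 1e-12)
    expect_true(all(r$x_bar >= 0 & r$x_bar <= 1))
  }
  res2 <- generate_trace(Zq, "abnormal", pl$lbc, pl$wae, cfg)
  expect_identical(res[[2]]$z_bar, res2[[2]]$z_bar)
  # optimizing a single query equals its row in the batched run
  one <- generate_trace(Zq[3, ], "abnormal", pl$lbc, pl$wae, cfg)
  expect_equal(one$z_bar, res[[3]]$z_bar, tolerance = 1e-10)
})

test_that("a huge proximity weight pins the counterfactual to the query", {
  pl <- demo_pipeline32()
  z <- pl$Zh[1, ]
  r <- generate_trace(z, "abnormal", pl$lbc, pl$wae,
                      cf_config(eta1 = 1e6, steps = 80))
  expect_lt(r$displacement, 0.05)
  rv <- generate_vanilla(z, "abnormal", pl$clf, pl$wae,
                         cf_config(eta1 = 1e6, steps = 80))
  expect_lt(rv$displacement, 0.05)
})

test_that("a self-consistent hypothesis requires almost no displacement", {
  pl <- demo_pipeline32()
  qix <- normal_queries(pl, 4)
  Zq <- encode(pl$wae, pl$ds$images[, , qix])
  # eta3 = 0 isolates proximity + hinge: with the hypothesis equal to the
  # model's own prediction the hinge is (near) zero at the query already
  cfg <- cf_config(eta3 = 0, steps = 150)
  same <- generate_trace(Zq, "normal", pl$lbc, pl$wae, cfg)
  flip <- generate_trace(Zq, "abnormal", pl$lbc, pl$wae, cfg)
  d_same <- median(vapply(same, `[[`, numeric(1), "displacement"))
  d_flip <- median(vapply(flip, `[[`, numeric(1), "displacement"))
  expect_lt(d_same, 0.1 * d_flip)
})

test_that("the vanilla generator descends its cross-entropy objective", {
  pl <- demo_pipeline32()
  qix <- normal_queries(pl, 3)
  Zq <- encode(pl$wae, pl$ds$images[, , qix])
  res <- generate_vanilla(Zq, "abnormal", pl$clf, pl$wae, cf_config(steps = 120))
  for (r in res) {
    expect_lte(r$objective, r$trajectory$objective[1] + 1e-12)
    # achieved target probability should not decrease relative to the query
    expect_gte(utils::tail(r$trajectory$prediction, 1),
               r$trajectory$prediction[1] - 1e-9)
  }
  expect_error(generate_vanilla(Zq, "bogus", pl$clf, pl$wae), "invalid target")
})

test_that("mixup endpoints and overconfidence tempering behave as defined", {
  # lambda endpoints are pure arithmetic on sample/label pairs
  z1 <- c(1, 2); z2 <- c(3, 4); y1 <- c(1, 0); y2 <- c(0, 1)
  expect_equal(1 * z1 + 0 * z2, z1)
  expect_equal(0.5 * y1 + 0.5 * y2, c(0.5, 0.5))
  pl <- demo_pipeline32()
  lab <- pl$ds$labels[pl$train_ix]
  mx <- train_mixup_classifier(pl$Z, lab, beta_param = 0.2,
                               clf_config(epochs = 40), seed = 4)
  p_mix <- class_probabilities(mx, pl$Zh)
  p_van <- class_probabilities(pl$clf, pl$Zh)
  expect_lte(mean(apply(p_mix, 1, max)), mean(apply(p_van, 1, max)) + 0.02)
  # mixup model still classifies
  acc <- mean((p_mix[, 2] > 0.5) == (pl$ds$labels[pl$holdout_ix] == "abnormal"))
  expect_gt(acc, 0.8)
  expect_error(train_mixup_classifier(pl$Z, lab, beta_param = -1), "beta_param")
})

test_that("the UWCC classifier trains and validates its inputs", {
  pl <- demo_pipeline32()
  lab <- pl$ds$labels[pl$train_ix]
  uw <- train_uwcc_classifier(pl$Z, lab, T_passes = 5,
                              clf_config(epochs = 30, dropout = 0.2), seed = 5)
  p <- class_probabilities(uw, pl$Zh)
  expect_gt(mean((p[, 2] > 0.5) == (pl$ds$labels[pl$holdout_ix] == "abnormal")), 0.8)
  expect_error(train_uwcc_classifier(pl$Z, lab, T_passes = 1), "T_passes")
  expect_error(train_uwcc_classifier(pl$Z, lab, T_passes = 5,
                                     clf_config(dropout = 0)), "dropout")
})

test_that("uncertainty weighting endpoints match their definitions", {
  # identical stochastic predictions: Bhattacharyya coefficient 1 per pass,
  # hence alpha = 1 - mean coefficient = 0 (pure cross entropy weighting)
  P <- matrix(c(0.7, 0.3), 3, 2, byrow = TRUE)
  Pbar <- P
  bc <- rowSums(sqrt(P * Pbar))
  expect_equal(bc, rep(1, 3), tolerance = 1e-12)
  expect_equal(pmin(pmax(1 - bc, 0), 1), rep(0, 3))
  # KL(U || P) = 0 iff P is uniform
  K <- 4; U <- rep(1 / K, K)
  kl <- function(p) sum(U * log(U / p))
  expect_equal(kl(U), 0)
  expect_gt(kl(c(0.7, 0.1, 0.1, 0.1)), 0)
})

test_that("gaussian-calibrated generation handles providers correctly", {
  pl <- demo_pipeline32()
  lab <- pl$ds$labels[pl$train_ix]
  qix <- normal_queries(pl, 3)
  Zq <- encode(pl$wae, pl$ds$images[, , qix])
  cfg <- cf_config(steps = 100)
  # ensemble of M = 1 without bootstrap equals the fixed-network objective up
  # to the (constant) floored-variance term: same minimizer trajectory
  p1 <- provider_ensemble(pl$Z, lab, M = 1, clf_config(epochs = 30), seed = 9)
  r1a <- generate_gaussian_calibrated(Zq, "abnormal", p1, pl$wae, cfg)
  r1b <- generate_gaussian_calibrated(Zq, "abnormal", p1, pl$wae, cfg)
  expect_identical(r1a[[1]]$z_bar, r1b[[1]]$z_bar)  # deterministic provider
  for (r in r1a) expect_lte(r$objective, r$trajectory$objective[1] + 1e-12)
  # MC dropout provider with fixed seeded masks is deterministic too
  dcl <- train_classifier(pl$Z, lab, clf_config(epochs = 30, dropout = 0.2),
                          seed = 10)
  pm <- provider_mc_dropout(dcl, T_passes = 5, seed = 3)
  rma <- generate_gaussian_calibrated(Zq, "abnormal", pm, pl$wae, cfg)
  rmb <- generate_gaussian_calibrated(Zq, "abnormal", pm, pl$wae, cfg)
  expect_identical(rma[[2]]$z_bar, rmb[[2]]$z_bar)
  expect_error(provider_mc_dropout(pl$clf), "dropout")
  # already-satisfied hypothesis: small displacement
  ab_ix <- utils::head(pl$holdout_ix[pl$ds$labels[pl$holdout_ix] == "abnormal"], 2)
  Zab <- encode(pl$wae, pl$ds$images[, , ab_ix])
  r_ok <- generate_gaussian_calibrated(Zab, "abnormal", p1, pl$wae, cfg)
  r_flip <- generate_gaussian_calibrated(Zab, "normal", p1, pl$wae, cfg)
  expect_lt(median(vapply(r_ok, `[[`, numeric(1), "displacement")),
            median(vapply(r_flip, `[[`, numeric(1), "displacement")))
})

test_that("a constant-variance provider reduces to the squared-error objective", {
  # hand-built provider machinery: two identical members give variance = floor,
  # so the data term is (y_bar - mu)^2 / (2 var) + const and the minimizer
  # matches plain least squares on mu
  pl <- demo_pipeline32()
  lab <- pl$ds$labels[pl$train_ix]
  set.seed(1)
  base <- train_classifier(pl$Z, lab, clf_config(epochs = 30), seed = 11)
  prov <- structure(list(type = "ensemble", members = list(base, base),
                         K = base$K, class_levels = base$class_levels,
                         latent_dim = base$latent_dim), class = "cf_provider")
  z <- pl$Zh[1, ]
  r <- generate_gaussian_calibrated(z, "abnormal", prov, NULL,
                                    cf_config(steps = 100))
  expect_equal(r$prediction$var, 1e-6, tolerance = 1e-12)
})

test_that("progressive sweep relaxes toward the hypothesis", {
  pl <- demo_pipeline32()
  z <- encode(pl$wae, pl$ds$images[, , normal_queries(pl, 1)])
  sw <- progressive_sweep(z, "abnormal", pl$lbc, pl$wae,
                          eta1_grid = c(0.5, 0.15, 0.05),
                          config = cf_config(steps = 120))
  expect_equal(nrow(sw$summary), 3)
  # singleton grid equals a single generate_trace call
  sw1 <- progressive_sweep(z, "abnormal", pl$lbc, pl$wae, eta1_grid = 0.3,
                           config = cf_config(steps = 120))
  direct <- generate_trace(z, "abnormal", pl$lbc, pl$wae,
                           cf_config(eta1 = 0.3, steps = 120))
  expect_identical(sw1$results[[1]]$z_bar, direct$z_bar)
  expect_error(progressive_sweep(z, "abnormal", pl$lbc, pl$wae,
                                 eta1_grid = c(0.1, 0.5)), "decreasing")
  expect_error(progressive_sweep(z, "abnormal", pl$lbc, pl$wae,
                                 eta1_grid = numeric(0)), "non-empty")
})
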