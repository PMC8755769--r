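# Shared fixtures, trained lazily once per test run and cached for every file
# that needs them. Sizes are desk scale: small enough to keep the suite fast,
# large enough that the models are scientifically meaningful.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small 32x32 pipeline for cheap counterfactual/metric tests
demo_pipeline32 <- function() {
  fixture("demo32", function() {
    ds <- generate_dataset(240, seed = 11, image_size = 32)
    tr <- 1:200; ho <- 201:240
    wae <- train_wae(ds$images[, , tr],
                     wae_config(image_size = 32, epochs = 12,
                                weight_switch_epoch = 4), seed = 2)
    Z <- encode(wae, ds$images[, , tr])
    lbc <- train_lbc(Z, ds$labels[tr], "classification",
                     lbc_config(f_hidden = c(128, 64), g_hidden = c(128, 64),
                                epochs = 30, latent_noise = 0.5), seed = 3)
    clf <- train_classifier(Z, ds$labels[tr], clf_config(epochs = 40), seed = 4)
    list(ds = ds, train_ix = tr, holdout_ix = ho, wae = wae, Z = Z,
         lbc = lbc, clf = clf,
         Zh = encode(wae, ds$images[, , ho]))
  })
}

# the 64x64 benchmark pipeline shared by the directional-comparison and
# progressive-sweep checks: 500 training images, scaled training
bench_pipeline64 <- function() {
  fixture("bench64", function() {
    ds <- generate_dataset(550, seed = 7, image_size = 64)
    tr <- 1:500; ho <- 501:550
    wae <- train_wae(ds$images[, , tr],
                     wae_config(epochs = 15, weight_switch_epoch = 5), seed = 8)
    Z <- encode(wae, ds$images[, , tr])
    lbc <- train_lbc(Z, ds$labels[tr], "classification",
                     lbc_config(f_hidden = c(128, 64), g_hidden = c(128, 64),
                                epochs = 30, latent_noise = 0.5), seed = 9)
    clf <- train_classifier(Z, ds$labels[tr], clf_config(epochs = 40), seed = 10)
    list(ds = ds, train_ix = tr, holdout_ix = ho, wae = wae, Z = Z,
         lbc = lbc, clf = clf,
         Zh = encode(wae, ds$images[, , ho]))
  })
}

# normal-class holdout queries from a pipeline fixture
normal_queries <- function(pl, n) {
  qix <- pl$holdout_ix[pl$ds$labels[pl$holdout_ix] == "normal"]
  utils::head(qix, n)
}

expect_grad_matches <- function(f, grad, x, n_probe = 10, eps = 1e-6,
                                tol = 1e-4, seed = 1) {
  set.seed(seed)
  idx <- sample(length(x), min(n_probe, length(x)))
  for (i in idx) {
    x2 <- x; x2[i] <- x[i] + eps; f1 <- f(x2)
    x2[i] <- x[i] - eps; f0 <- f(x2)
    expect_lt(abs((f1 - f0) / (2 * eps) - grad[i]), tol)
  }
}
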