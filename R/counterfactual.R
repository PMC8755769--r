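# Counterfactual generation in the autoencoder's latent space.
#
# The calibration-driven (TraCE) objective optimizes a latent code z_hat so
# that the desired target y_bar falls inside the margin-shrunk prediction
# interval [F(z_hat) - G(z_hat) + tau, F(z_hat) + G(z_hat) - tau], while
# staying close to the query and penalizing wide intervals:
#   eta1 ||z - z_hat||^2 + eta2 hinge(F, G, y_bar) + eta3 sum(G(z_hat)).
# Baselines share the same Adam-on-latent loop and differ only in the data
# term: cross entropy (vanilla / mixup / UWCC) or a heteroscedastic Gaussian
# likelihood driven by an uncertainty provider (MC dropout, deep ensembles).

#' Counterfactual optimization configuration
#'
#' @param eta1 weight of the latent proximity term (default 0.5).
#' @param eta2 weight of the prediction/data term (default 0.5).
#' @param eta3 weight of the interval-width penalty (default 0.2; TraCE only).
#' @param tau hinge margin (default 0.05).
#' @param steps maximum Adam steps on the latent code (default 300).
#' @param lr Adam learning rate on the latent code (default 0.05).
#' @param patience steps without objective improvement before early stop.
#' @param seed integer seed (only consulted by stochastic providers).
#' @return object of class `cf_config`.
#' @export
cf_config <- function(eta1 = 0.5, eta2 = 0.5, eta3 = 0.2, tau = 0.05,
                      steps = 300L, lr = 0.05, patience = 30L, seed = 1L) {
  if (any(c(eta1, eta2, eta3) < 0)) stop("cf weights must be nonnegative")
  if (steps < 1) stop("steps must be >= 1")
  structure(list(eta1 = eta1, eta2 = eta2, eta3 = eta3, tau = tau,
                 steps = as.integer(steps), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cf_config")
}

# normalize a target hypothesis to the model's native output scale:
# classification -> logit-encoded row vector; regression -> standardized value
encode_hypothesis <- function(model, y_bar) {
  if (model$task == "classification") {
    if (is.character(y_bar) || is.factor(y_bar)) {
      k <- match(as.character(y_bar), model$class_levels)
      if (is.na(k)) stop("unknown class: ", y_bar)
    } else k <- as.integer(y_bar)
    if (k < 1 || k > model$K) stop("class index out of range")
    list(Y = labels_to_logits(k, model$K, model$config$eps_negative),
         class_index = k)
  } else {
    list(Y = matrix((as.numeric(y_bar) - model$center) / model$scale, 1, 1),
         class_index = NA_integer_)
  }
}

#' Calibration-driven counterfactual objective
#'
#' Evaluates `eta1 * ||z - z_hat||^2 + eta2 * [max(0, (y_hat - delta) - y_bar
#' + tau) + max(0, y_bar - (y_hat + delta) + tau)] + eta3 * delta` with
#' `y_hat = F(z_hat)`, `delta = G(z_hat)`; for multi-output models the hinge
#' and width terms sum over outputs. Classification hypotheses are encoded as
#' logit targets; regression hypotheses on the model's standardized scale.
#'
#' @param z_hat candidate latent (vector or N x d matrix).
#' @param z query latent (same shape).
#' @param model a trained [train_lbc()] model.
#' @param y_bar target hypothesis: class label/index or numeric value.
#' @param config a [cf_config()].
#' @return scalar objective (or vector, one per row).
#' @export
trace_cf_objective <- function(z_hat, z, model, y_bar, config = cf_config()) {
  stopifnot(inherits(model, "lbc_model"))
  single <- is.null(dim(z_hat))
  Zh <- if (single) matrix(z_hat, nrow = 1) else as.matrix(z_hat)
  Z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  hyp <- encode_hypothesis(model, y_bar)
  Y <- hyp$Y[rep(1, nrow(Zh)), , drop = FALSE]
  yh <- net_forward(model$F_net, Zh)$out
  dl <- net_forward(model$G_net, Zh)$out
  lo <- pmax(0, (yh - dl) - Y + config$tau)
  hi <- pmax(0, Y - (yh + dl) + config$tau)
  hinge <- rowSums(matrix(lo + hi, nrow(Zh)))
  obj <- config$eta1 * rowSums((Z - Zh)^2) + config$eta2 * hinge +
    config$eta3 * rowSums(matrix(dl, nrow(Zh)))
  if (single) obj[1] else obj
}

# shared Adam descent on latent codes; fns take/return matrices (rows = queries)
cf_optimize <- function(Z0, obj_grad_fn, config, pred_fn = NULL) {
  Zh <- Z0
  st <- adam_init(list(Zh))
  n <- nrow(Z0)
  best_obj <- rep(Inf, n)
  best_Z <- Z0
  traj_obj <- matrix(NA_real_, config$steps, n)
  traj_pred <- matrix(NA_real_, config$steps, n)
  stall <- 0L
  steps_done <- 0L
  for (s in seq_len(config$steps)) {
    og <- obj_grad_fn(Zh)
    if (any(!is.finite(og$obj))) {
      stop("counterfactual optimization aborted: non-finite objective at step ", s)
    }
    traj_obj[s, ] <- og$obj
    if (!is.null(pred_fn)) traj_pred[s, ] <- pred_fn(Zh)
    improved <- og$obj < best_obj - 1e-10
    if (any(improved)) {
      best_Z[improved, ] <- Zh[improved, , drop = FALSE]
      best_obj[improved] <- og$obj[improved]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    steps_done <- s
    if (stall >= config$patience) break
    upd <- adam_step(list(Zh), list(og$grad), st, config$lr)
    Zh <- upd$params[[1]]
    st <- upd$state
  }
  list(z_bar = best_Z, objective = best_obj,
       traj_obj = traj_obj[seq_len(steps_done), , drop = FALSE],
       traj_pred = traj_pred[seq_len(steps_done), , drop = FALSE],
       steps = steps_done)
}

cf_result_from <- function(Z, opt, wae, model_pred, i, method) {
  xb <- if (!is.null(wae)) decode(wae, opt$z_bar[i, ]) else NULL
  structure(list(
    method = method,
    z = Z[i, ], z_bar = opt$z_bar[i, ], x_bar = xb,
    trajectory = data.frame(step = seq_len(opt$steps),
                            objective = opt$traj_obj[, i],
                            prediction = opt$traj_pred[, i]),
    objective = opt$objective[i],
    displacement = sqrt(sum((Z[i, ] - opt$z_bar[i, ])^2)),
    prediction = model_pred(opt$z_bar[i, , drop = FALSE])
  ), class = "cf_result")
}

#' @export
print.cf_result <- function(x, ...) {
  cat("cf_result (", x$method, "): ", nrow(x$trajectory), " steps, objective ",
      format(x$objective, digits = 4), ", latent displacement ",
      format(x$displacement, digits = 4), "\n", sep = "")
  invisible(x)
}

wrap_results <- function(Z, opt, wae, model_pred, method, single) {
  res <- lapply(seq_len(nrow(Z)), function(i)
    cf_result_from(Z, opt, wae, model_pred, i, method))
  if (single) res[[1]] else structure(res, class = "cf_result_set")
}

#' Generate a calibration-driven (TraCE) counterfactual
#'
#' Gradient-descends the calibration objective (see [trace_cf_objective()])
#' over the latent code, starting at the query; F, G and the autoencoder stay
#' frozen. Returns the best-objective iterate (earliest step on ties) and its
#' decoded image.
#'
#' @param z query latent (vector), or an N x d matrix to optimize a batch of
#'   independent queries in one call (rows never interact).
#' @param y_bar target hypothesis: class label/index (classification) or
#'   numeric value (regression).
#' @param model a trained [train_lbc()] model.
#' @param wae the [train_wae()] model used for decoding (optional: `NULL`
#'   skips decoding).
#' @param config a [cf_config()].
#' @return a `cf_result` (list of them for matrix input) with fields `z`,
#'   `z_bar`, `x_bar`, `trajectory` (step, objective, prediction),
#'   `objective`, `displacement` and the achieved `prediction` (y_hat, delta).
#' @export
generate_trace <- function(z, y_bar, model, wae = NULL, config = cf_config()) {
  stopifnot(inherits(model, "lbc_model"))
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  hyp <- encode_hypothesis(model, y_bar)
  Y <- hyp$Y[rep(1, nrow(Z)), , drop = FALSE]
  e1 <- config$eta1; e2 <- config$eta2; e3 <- config$eta3; tau <- config$tau
  obj_grad <- function(Zh) {
    Ff <- net_forward(model$F_net, Zh)
    Gf <- net_forward(model$G_net, Zh)
    yh <- Ff$out; dl <- Gf$out
    lo_act <- ((yh - dl) - Y + tau) > 0
    hi_act <- (Y - (yh + dl) + tau) > 0
    lo <- pmax(0, (yh - dl) - Y + tau); hi <- pmax(0, Y - (yh + dl) + tau)
    obj <- e1 * rowSums((Z - Zh)^2) +
      e2 * rowSums(matrix(lo + hi, nrow(Zh))) +
      e3 * rowSums(matrix(dl, nrow(Zh)))
    dY_hat <- e2 * (lo_act - hi_act)
    dDelta <- e2 * (-(lo_act + hi_act)) + e3
    gF <- net_backward(model$F_net, Ff$cache, dY_hat)$dX
    gG <- net_backward(model$G_net, Gf$cache, dDelta)$dX
    list(obj = obj, grad = 2 * e1 * (Zh - Z) + gF + gG)
  }
  pred_fn <- if (model$task == "classification") {
    function(Zh) class_probabilities(model, Zh)[, hyp$class_index]
  } else {
    function(Zh) predict(model, Zh)$y_hat[, 1]
  }
  opt <- cf_optimize(Z, obj_grad, config, pred_fn)
  model_pred <- function(zz) predict(model, zz)
  wrap_results(Z, opt, wae, model_pred, "trace", single)
}

#' Progressive decision-boundary sweep
#'
#' Generates one counterfactual per value of a strictly decreasing
#' `eta1_grid` (relaxing the proximity constraint progressively pushes the
#' prediction toward the hypothesis), reporting the achieved target
#' probability (or value) at each step.
#'
#' @inheritParams generate_trace
#' @param eta1_grid strictly decreasing vector of proximity weights.
#' @return list with `results` (one `cf_result` per eta1) and `summary`
#'   (data.frame: eta1, prediction, displacement).
#' @export
progressive_sweep <- function(z, y_bar, model, wae = NULL,
                              eta1_grid = c(0.5, 0.3, 0.15, 0.05),
                              config = cf_config()) {
  if (length(eta1_grid) < 1) stop("eta1_grid must be non-empty")
  if (length(eta1_grid) > 1 && any(diff(eta1_grid) >= 0)) {
    stop("eta1_grid must be strictly decreasing")
  }
  results <- vector("list", length(eta1_grid))
  for (j in seq_along(eta1_grid)) {
    cfg_j <- config; cfg_j$eta1 <- eta1_grid[j]
    results[[j]] <- generate_trace(z, y_bar, model, wae, cfg_j)
  }
  pred <- vapply(results, function(r) {
    tr <- if (inherits(r, "cf_result")) r else r[[1]]
    utils::tail(tr$trajectory$prediction, 1)
  }, numeric(1))
  disp <- vapply(results, function(r) {
    tr <- if (inherits(r, "cf_result")) r else r[[1]]
    tr$displacement
  }, numeric(1))
  list(results = results,
       summary = data.frame(eta1 = eta1_grid, prediction = pred,
                            displacement = disp))
}

# ---- baseline classifiers ----------------------------------------------------

#' Baseline latent-space classifier configuration
#'
#' @param hidden hidden widths (default c(128, 64), ELU).
#' @param epochs,lr,batch_size training schedule.
#' @param dropout dropout rate on hidden layers (needed for MC dropout and
#'   UWCC; default 0).
#' @param latent_noise standard deviation of Gaussian training jitter on the
#'   latent codes (default 0.5; see [lbc_config()] for the rationale).
#' @return object of class `clf_config`.
#' @export
clf_config <- function(hidden = c(128L, 64L), epochs = 60L, lr = 1e-3,
                       batch_size = 64L, dropout = 0, latent_noise = 0.5) {
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1, latent_noise >= 0)
  structure(list(hidden = hidden, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 latent_noise = latent_noise),
            class = "clf_config")
}

labels_to_index <- function(labels) {
  if (is.factor(labels)) {
    list(idx = as.integer(labels), levels = levels(labels))
  } else {
    lv <- sort(unique(labels))
    list(idx = as.integer(factor(labels, levels = lv)), levels = as.character(lv))
  }
}

draw_dropout_masks <- function(net, n, rate) {
  if (rate <= 0) return(NULL)
  lapply(seq_len(length(net$layers) - 1L), function(l) {
    w <- ncol(net$layers[[l]]$W)
    matrix(stats::rbinom(n * w, 1, 1 - rate) / (1 - rate), n, w)
  })
}

# core cross-entropy trainer; `mix` adds mixup, `uwcc` adds the
# uncertainty-weighted confidence-calibration term
train_clf_core <- function(latents, labels, config, seed, mode = "vanilla",
                           beta_param = 0.2, T_passes = 5L) {
  Z <- as.matrix(latents)
  li <- labels_to_index(labels)
  K <- length(li$levels)
  if (K < 2) stop("need at least 2 classes")
  onehot <- diag(K)[li$idx, , drop = FALSE]
  net <- dense_net(c(ncol(Z), config$hidden, K),
                   c(rep("elu", length(config$hidden)), "linear"),
                   seed = seed_stream(seed, "clf"))
  p <- net_params(net); opt <- adam_init(p)
  bs <- min(config$batch_size, nrow(Z))
  set.seed(seed_stream(seed, "clf_train"))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nrow(Z))
    for (start in seq(1, nrow(Z), by = bs)) {
      ix <- ord[start:min(start + bs - 1L, nrow(Z))]
      Zb <- Z[ix, , drop = FALSE]; Yb <- onehot[ix, , drop = FALSE]
      nb <- length(ix)
      if (config$latent_noise > 0) {
        Zb <- Zb + matrix(stats::rnorm(length(Zb), sd = config$latent_noise), nb)
      }
      if (mode == "mixup") {
        lam <- stats::rbeta(nb, beta_param, beta_param)
        perm <- sample.int(nb)
        Zb <- lam * Zb + (1 - lam) * Zb[perm, , drop = FALSE]
        Yb <- lam * Yb + (1 - lam) * Yb[perm, , drop = FALSE]
      }
      net_c <- net_set_params(net, p)
      if (mode == "uwcc") {
        # T stochastic passes; alpha_i = 1 - mean Bhattacharyya coefficient
        passes <- lapply(seq_len(T_passes), function(t) {
          masks <- draw_dropout_masks(net_c, nb, config$dropout)
          fw <- net_forward(net_c, Zb, masks)
          list(fw = fw, masks = masks, P = softmax(fw$out))
        })
        Pbar <- Reduce(`+`, lapply(passes, `[[`, "P")) / T_passes
        bc <- rowMeans(vapply(passes, function(ps)
          rowSums(sqrt(pmax(ps$P * Pbar, 0))), numeric(nb)))
        a_i <- pmin(pmax(1 - bc, 0), 1)
        U <- 1 / K
        grads <- NULL
        for (ps in passes) {
          dlogit <- ((1 - a_i) * (ps$P - Yb) + a_i * (ps$P - U)) / (nb * T_passes)
          bw <- net_backward(net_c, ps$fw$cache, dlogit, ps$masks)
          g <- net_grads_flat(bw$grads)
          grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        }
      } else {
        masks <- draw_dropout_masks(net_c, nb, config$dropout)
        fw <- net_forward(net_c, Zb, masks)
        P <- softmax(fw$out)
        dlogit <- (P - Yb) / nb
        bw <- net_backward(net_c, fw$cache, dlogit, masks)
        grads <- net_grads_flat(bw$grads)
      }
      st <- adam_step(p, grads, opt, config$lr)
      p <- st$params; opt <- st$state
    }
  }
  structure(list(net = net_set_params(net, p), K = K, class_levels = li$levels,
                 config = config, latent_dim = ncol(Z), mode = mode,
                 task = "classification"),
            class = "latent_classifier")
}

#' Train a plain latent-space classifier (vanilla baseline)
#'
#' Softmax cross entropy, no calibration or uncertainty estimation.
#'
#' @param latents N x d matrix of latent codes.
#' @param labels class labels (factor or vector).
#' @param config a [clf_config()]; set `dropout > 0` if the classifier will
#'   be used with MC dropout.
#' @param seed integer seed.
#' @return object of class `latent_classifier`.
#' @export
train_classifier <- function(latents, labels, config = clf_config(), seed = 1L) {
  train_clf_core(latents, labels, config, seed, mode = "vanilla")
}

#' Train a mixup-regularized classifier
#'
#' Each minibatch is replaced by convex combinations `lambda * z_i +
#' (1 - lambda) * z_j` of random sample pairs with correspondingly mixed
#' one-hot labels, `lambda ~ Beta(beta_param, beta_param)`; this tempers
#' overconfidence. Counterfactuals for this model use [generate_vanilla()].
#'
#' @inheritParams train_classifier
#' @param beta_param shape of the symmetric Beta mixing distribution (> 0).
#' @export
train_mixup_classifier <- function(latents, labels, beta_param = 0.2,
                                   config = clf_config(), seed = 1L) {
  if (!is.numeric(beta_param) || beta_param <= 0) stop("beta_param must be > 0")
  train_clf_core(latents, labels, config, seed, mode = "mixup",
                 beta_param = beta_param)
}

#' Train an uncertainty-weighted confidence-calibrated (UWCC) classifier
#'
#' Per-sample loss `(1 - alpha_i) * CE + alpha_i * KL(U || P)` where U is the
#' uniform distribution and `alpha_i = 1 - mean Bhattacharyya coefficient`
#' between each of T stochastic (dropout) predictions and their mean, clipped
#' to \[0,1\] — identical passes give coefficient 1 and hence `alpha_i = 0`
#' (pure cross entropy); disagreeing passes push the prediction toward
#' uniform. Counterfactuals use [generate_vanilla()].
#'
#' @inheritParams train_classifier
#' @param T_passes number of stochastic forward passes (>= 2).
#' @export
train_uwcc_classifier <- function(latents, labels, T_passes = 5L,
                                  config = clf_config(dropout = 0.2), seed = 1L) {
  if (T_passes < 2) stop("T_passes must be >= 2")
  if (config$dropout <= 0) stop("UWCC requires dropout > 0 in the network")
  train_clf_core(latents, labels, config, seed, mode = "uwcc",
                 T_passes = T_passes)
}

#' @export
class_probabilities.latent_classifier <- function(model, z) {
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(Z) != model$latent_dim) stop("latent dimension mismatch")
  p <- softmax(net_forward(model$net, Z)$out)
  if (single) drop(p) else p
}

#' @export
print.latent_classifier <- function(x, ...) {
  cat("latent_classifier (", x$mode, "): K =", x$K, ", hidden",
      paste(x$config$hidden, collapse = ","), "\n")
  invisible(x)
}

#' Generate a vanilla cross-entropy counterfactual
#'
#' Minimizes `eta1 ||z - z_hat||^2 + eta2 * CE(softmax(F(z_hat)), y_bar)`
#' for a classifier trained without calibration.
#'
#' @param z query latent vector (or N x d matrix of queries).
#' @param y_bar_class target class (label or index).
#' @param classifier a [train_classifier()] (or mixup/UWCC) model.
#' @param wae decoder model, or `NULL`.
#' @param config a [cf_config()] (`eta3` is ignored).
#' @return `cf_result` (or list for matrix input).
#' @export
generate_vanilla <- function(z, y_bar_class, classifier, wae = NULL,
                             config = cf_config()) {
  stopifnot(inherits(classifier, "latent_classifier"))
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  if (is.character(y_bar_class) || is.factor(y_bar_class)) {
    k <- match(as.character(y_bar_class), classifier$class_levels)
  } else k <- as.integer(y_bar_class)
  if (is.na(k) || k < 1 || k > classifier$K) stop("invalid target class")
  e1 <- config$eta1; e2 <- config$eta2
  obj_grad <- function(Zh) {
    fw <- net_forward(classifier$net, Zh)
    P <- softmax(fw$out)
    ce <- -log(pmax(P[, k], 1e-12))
    onehot <- matrix(0, nrow(Zh), classifier$K); onehot[, k] <- 1
    gZ <- net_backward(classifier$net, fw$cache, e2 * (P - onehot))$dX
    list(obj = e1 * rowSums((Z - Zh)^2) + e2 * ce,
         grad = 2 * e1 * (Zh - Z) + gZ)
  }
  pred_fn <- function(Zh) class_probabilities(classifier, Zh)[, k]
  opt <- cf_optimize(Z, obj_grad, config, pred_fn)
  model_pred <- function(zz) list(probabilities = class_probabilities(classifier, zz))
  wrap_results(Z, opt, wae, model_pred, paste0("vanilla/", classifier$mode), single)
}

# ---- uncertainty providers (MC dropout / deep ensembles) ---------------------

# A provider maps a latent batch to the mean/variance of the target-class
# logit across stochastic passes or ensemble members, together with the
# gradients of both w.r.t. the latent. Variance is floored for stability.
provider_stats <- function(fws, nets, masks_list, k, Zh, var_floor = 1e-6) {
  M <- length(nets)
  n <- nrow(Zh)
  f <- matrix(NA_real_, n, M)
  gs <- vector("list", M)
  for (m in seq_len(M)) {
    f[, m] <- fws[[m]]$out[, k]
    dY <- matrix(0, n, ncol(fws[[m]]$out)); dY[, k] <- 1
    gs[[m]] <- net_backward(nets[[m]], fws[[m]]$cache, dY, masks_list[[m]])$dX
  }
  mu <- rowMeans(f)
  dmu <- Reduce(`+`, gs) / M
  v <- rowMeans((f - mu)^2) + var_floor
  dvar <- Reduce(`+`, lapply(seq_len(M), function(m)
    2 * (f[, m] - mu) * (gs[[m]] - dmu))) / M
  list(mu = mu, var = v, dmu = dmu, dvar = dvar)
}

#' Deep-ensemble uncertainty provider
#'
#' Trains `M` classifiers with bootstrap resampling and different
#' initializations; at optimization time the target-class logit's ensemble
#' mean and variance (and their latent gradients) drive the heteroscedastic
#' objective of [generate_gaussian_calibrated()].
#'
#' @param latents,labels training data.
#' @param M ensemble size (default 5).
#' @param config a [clf_config()].
#' @param seed integer seed.
#' @return object of class `cf_provider`.
#' @export
provider_ensemble <- function(latents, labels, M = 5L, config = clf_config(),
                              seed = 1L) {
  Z <- as.matrix(latents)
  members <- vector("list", M)
  for (m in seq_len(M)) {
    set.seed(seed_stream(seed, paste0("boot", m)))
    ix <- if (M > 1) sample.int(nrow(Z), replace = TRUE) else seq_len(nrow(Z))
    members[[m]] <- train_classifier(Z[ix, , drop = FALSE],
                                     labels[ix],
                                     config, seed = seed_stream(seed, paste0("member", m)))
  }
  structure(list(type = "ensemble", members = members,
                 K = members[[1]]$K, class_levels = members[[1]]$class_levels,
                 latent_dim = members[[1]]$latent_dim),
            class = "cf_provider")
}

#' Monte Carlo dropout uncertainty provider
#'
#' Wraps a dropout-trained classifier; `T_passes` dropout masks are drawn
#' once (seeded) and held fixed during counterfactual optimization, making
#' the provider deterministic given the seed.
#'
#' @param classifier a [train_classifier()] model trained with `dropout > 0`.
#' @param T_passes number of stochastic passes (default 5).
#' @param seed integer seed for the fixed masks.
#' @export
provider_mc_dropout <- function(classifier, T_passes = 5L, seed = 1L) {
  stopifnot(inherits(classifier, "latent_classifier"))
  if (classifier$config$dropout <= 0) {
    stop("MC dropout requires a classifier trained with dropout > 0")
  }
  structure(list(type = "mc_dropout", classifier = classifier,
                 T_passes = as.integer(T_passes), seed = as.integer(seed),
                 K = classifier$K, class_levels = classifier$class_levels,
                 latent_dim = classifier$latent_dim),
            class = "cf_provider")
}

#' Generate a counterfactual under a heteroscedastic Gaussian objective
#'
#' Minimizes `eta1 ||z - z_hat||^2 + eta2 * [(y_bar - mu)^2 / (2 sigma^2) +
#' log(sigma^2) / 2]` where `(mu, sigma^2)` are the mean/variance of the
#' target-class logit across the provider's stochastic passes (MC dropout) or
#' ensemble members. The variance is floored at `1e-6`.
#'
#' @param z query latent vector (or matrix of queries).
#' @param y_bar target hypothesis (class label/index; its logit encoding is
#'   the regression target for the data term).
#' @param provider a [provider_ensemble()] or [provider_mc_dropout()].
#' @param wae decoder model, or `NULL`.
#' @param config a [cf_config()].
#' @export
generate_gaussian_calibrated <- function(z, y_bar, provider, wae = NULL,
                                         config = cf_config()) {
  stopifnot(inherits(provider, "cf_provider"))
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  if (is.character(y_bar) || is.factor(y_bar)) {
    k <- match(as.character(y_bar), provider$class_levels)
  } else k <- as.integer(y_bar)
  if (is.na(k) || k < 1 || k > provider$K) stop("invalid target class")
  ybar_val <- labels_to_logits(k, provider$K, 0.01)[1, k]
  if (provider$type == "ensemble") {
    nets <- lapply(provider$members, `[[`, "net")
    masks_for <- function(n) rep(list(NULL), length(nets))
  } else {
    nets <- rep(list(provider$classifier$net), provider$T_passes)
    set.seed(provider$seed)
    fixed_masks <- lapply(seq_len(provider$T_passes), function(t)
      draw_dropout_masks(provider$classifier$net, nrow(Z),
                         provider$classifier$config$dropout))
    masks_for <- function(n) lapply(fixed_masks, function(ms)
      lapply(ms, function(m) m[seq_len(n), , drop = FALSE]))
  }
  e1 <- config$eta1; e2 <- config$eta2
  obj_grad <- function(Zh) {
    ml <- masks_for(nrow(Zh))
    fws <- lapply(seq_along(nets), function(m) net_forward(nets[[m]], Zh, ml[[m]]))
    stp <- provider_stats(fws, nets, ml, k, Zh)
    data_term <- (ybar_val - stp$mu)^2 / (2 * stp$var) + 0.5 * log(stp$var)
    d_mu <- -(ybar_val - stp$mu) / stp$var
    d_var <- -(ybar_val - stp$mu)^2 / (2 * stp$var^2) + 0.5 / stp$var
    gZ <- e2 * (d_mu * stp$dmu + d_var * stp$dvar)
    list(obj = e1 * rowSums((Z - Zh)^2) + e2 * data_term,
         grad = 2 * e1 * (Zh - Z) + gZ)
  }
  pred_fn <- function(Zh) {
    ml <- masks_for(nrow(Zh))
    P <- Reduce(`+`, lapply(seq_along(nets), function(m)
      softmax(net_forward(nets[[m]], Zh, ml[[m]])$out))) / length(nets)
    P[, k]
  }
  opt <- cf_optimize(Z, obj_grad, config, pred_fn)
  model_pred <- function(zz) {
    ml <- masks_for(nrow(zz))
    fws <- lapply(seq_along(nets), function(m) net_forward(nets[[m]], zz, ml[[m]]))
    stp <- provider_stats(fws, nets, ml, k, zz)
    list(mu = stp$mu, var = stp$var)
  }
  wrap_results(Z, opt, wae, model_pred,
               paste0("gaussian/", provider$type), single)
}
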