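# Learn-by-Calibrating: a predictor F (point estimates; logits for
# classification) and an interval estimator G (half-widths delta >= 0) trained
# by alternating two objectives on latent codes:
#   phi-step (G):  empirical interval calibration error
#                  sum_k | alpha - (1/N) sum_i 1[ y in [y_hat - d, y_hat + d] ] |
#                  (a sigmoid-smoothed indicator supplies gradients; all
#                  reported calibration numbers use the hard indicator)
#   theta-step (F): hinge loss pushing each target inside the margin-shrunk
#                  interval [y_hat - d + tau, y_hat + d - tau].
# Classification reuses the same machinery by encoding labels as logits.

#' LbC training configuration
#'
#' @param alpha target interval confidence level in (0,1) (default 0.9).
#' @param tau hinge margin (default 0.05).
#' @param eps_negative probability floor assigned to negative classes when
#'   encoding labels as logits (default 0.01).
#' @param f_hidden,g_hidden hidden widths of the predictor and interval
#'   networks (defaults \[512,1024,256,128,64,16\] with ELU and
#'   \[512,1024,256,128,64\] with ReLU; the output layer of size K is
#'   appended automatically).
#' @param epochs maximum alternation rounds (one G epoch + one F epoch each).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param surrogate gradient surrogate for the non-differentiable coverage
#'   indicator in G's objective: `"quantile"` (default; pinball loss on the
#'   absolute residual, whose minimizer is the alpha-quantile and therefore
#'   the exact optimum of the hard calibration objective) or `"sigmoid"`
#'   (product-of-sigmoids smoothing; saturates once intervals are very wide,
#'   which can stall training — kept for comparison).
#' @param surrogate_temperature temperature of the sigmoid-smoothed coverage
#'   indicator (default 10; used only with `surrogate = "sigmoid"`).
#' @param patience alternation rounds without improvement of the validation
#'   score (calibration error + hinge) before stopping (default 10).
#' @param val_fraction fraction of the training data held out for the
#'   convergence check.
#' @param latent_noise standard deviation of Gaussian jitter added to the
#'   predictor's (theta-step) training batches (default 0; the interval
#'   network always trains on clean codes so calibration reflects the data
#'   distribution). When F is trained on autoencoder latents at desk scale, a
#'   few hundred codes cannot constrain its boundary in a 100-dimensional
#'   space; jitter (e.g. 0.5) fills the neighborhood of the data manifold
#'   with label-consistent targets so counterfactual gradients follow
#'   semantic directions instead of adversarial ones.
#' @return an object of class `lbc_config`.
#' @export
lbc_config <- function(alpha = 0.9, tau = 0.05, eps_negative = 0.01,
                       f_hidden = c(512L, 1024L, 256L, 128L, 64L, 16L),
                       g_hidden = c(512L, 1024L, 256L, 128L, 64L),
                       epochs = 150L, lr = 1e-3, batch_size = 64L,
                       surrogate = c("quantile", "sigmoid"),
                       surrogate_temperature = 10,
                       patience = 10L, val_fraction = 0.15,
                       latent_noise = 0) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (tau < 0) stop("tau must be >= 0")
  if (eps_negative <= 0 || eps_negative >= 1) stop("invalid eps_negative")
  structure(list(alpha = alpha, tau = tau, eps_negative = eps_negative,
                 f_hidden = f_hidden, g_hidden = g_hidden,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 surrogate = match.arg(surrogate),
                 surrogate_temperature = surrogate_temperature,
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 latent_noise = latent_noise),
            class = "lbc_config")
}

#' Encode class labels as logit targets
#'
#' Negative classes receive probability `eps_negative`, the positive class
#' `1 - (K-1) * eps_negative` (so the vector sums to one), and each
#' probability p is mapped to `log(p / (1 - p))`. This makes interval
#' calibration, which is defined for continuous targets, applicable to
#' classification by operating on the logits directly.
#'
#' @param label class index in 1..K (vectorized).
#' @param K number of classes (>= 2).
#' @param eps_negative probability floor for negative classes;
#'   `eps_negative * (K - 1)` must be < 1.
#' @return an N x K matrix of logit targets.
#' @export
#' @examples
#' labels_to_logits(1, K = 2)  # c(log(99), -log(99)) approximately (4.595, -4.595)
labels_to_logits <- function(label, K, eps_negative = 0.01) {
  if (K < 2) stop("K must be >= 2")
  if (eps_negative <= 0 || eps_negative >= 1 / K) {
    stop("invalid eps_negative: need 0 < eps_negative < 1/K")
  }
  if (any(label < 1 | label > K)) stop("label out of range 1..K")
  p_pos <- 1 - (K - 1) * eps_negative
  out <- matrix(log(eps_negative / (1 - eps_negative)), length(label), K)
  out[cbind(seq_along(label), label)] <- log(p_pos / (1 - p_pos))
  out
}

#' Empirical interval calibration error (hard indicator)
#'
#' `sum_k | alpha - (1/N) sum_i 1[y_hat[i,k] - delta[i,k] <= y[i,k] <=
#' y_hat[i,k] + delta[i,k]] |`. This is the exact evaluation-path value; a
#' smoothed surrogate (see [lbc_config()]) is used for gradients only.
#'
#' @param y_hat,delta,y N x K matrices (or vectors for K = 1) of point
#'   estimates, half-widths and targets.
#' @param alpha target confidence level.
#' @return scalar calibration error.
#' @export
interval_calibration_error <- function(y_hat, delta, y, alpha) {
  y_hat <- as.matrix(y_hat); delta <- as.matrix(delta); y <- as.matrix(y)
  if (!all(dim(y_hat) == dim(delta)) || !all(dim(y_hat) == dim(y))) {
    stop("interval_calibration_error: shape mismatch")
  }
  covered <- (y >= y_hat - delta) & (y <= y_hat + delta)
  sum(abs(alpha - colMeans(covered)))
}

#' Hinge interval loss
#'
#' Mean over samples, summed over outputs, of
#' `max(0, (y_hat - delta) - y + tau) + max(0, y - (y_hat + delta) + tau)`.
#' Zero iff every target lies inside the margin-shrunk interval
#' `[y_hat - delta + tau, y_hat + delta - tau]`.
#'
#' @inheritParams interval_calibration_error
#' @param tau hinge margin.
#' @return scalar loss.
#' @export
hinge_interval_loss <- function(y_hat, delta, y, tau) {
  y_hat <- as.matrix(y_hat); delta <- as.matrix(delta); y <- as.matrix(y)
  if (!all(dim(y_hat) == dim(delta)) || !all(dim(y_hat) == dim(y))) {
    stop("hinge_interval_loss: shape mismatch")
  }
  h <- pmax(0, (y_hat - delta) - y + tau) + pmax(0, y - (y_hat + delta) + tau)
  dim(h) <- dim(y)   # pmax against the scalar 0 drops dim attributes
  sum(colMeans(h))
}

# smoothed coverage s_ik and its derivative w.r.t. delta and y_hat
smooth_coverage <- function(y_hat, delta, y, t) {
  s1 <- sigmoid(t * (y - (y_hat - delta)))
  s2 <- sigmoid(t * ((y_hat + delta) - y))
  s <- s1 * s2
  d1 <- t * s1 * (1 - s1) * s2
  d2 <- t * s2 * (1 - s2) * s1
  list(s = s, d_delta = d1 + d2, d_yhat = -d1 + d2)
}

#' Train a calibrated predictor pair by alternating optimization
#'
#' Alternates one epoch of interval-network updates (smoothed calibration
#' error, predictor frozen) with one epoch of predictor updates (hinge loss,
#' intervals frozen), until the validation hinge loss stops improving.
#' Regression targets are standardized internally and de-standardized at the
#' interface; the interval network output passes through softplus so
#' half-widths are nonnegative.
#'
#' @param latents N x d matrix of latent codes.
#' @param targets class labels (factor or integer 1..K) for classification;
#'   numeric vector for regression.
#' @param task `"classification"` or `"regression"`.
#' @param config an [lbc_config()].
#' @param seed integer seed.
#' @return an object of class `lbc_model`.
#' @export
train_lbc <- function(latents, targets,
                      task = c("classification", "regression"),
                      config = lbc_config(), seed = 1L) {
  task <- match.arg(task)
  latents <- as.matrix(latents)
  n <- nrow(latents); d <- ncol(latents)
  if (length(unique(targets)) < 2) {
    stop("train_lbc: targets are degenerate (fewer than 2 distinct values)")
  }
  if (task == "classification") {
    if (is.factor(targets)) {
      class_levels <- levels(targets)
      lab <- as.integer(targets)
    } else {
      class_levels <- as.character(sort(unique(targets)))
      lab <- as.integer(factor(targets, levels = sort(unique(targets))))
    }
    K <- length(class_levels)
    Y <- labels_to_logits(lab, K, config$eps_negative)
    center <- rep(0, K); scale <- rep(1, K)
  } else {
    class_levels <- NULL
    K <- 1L
    center <- mean(targets); scale <- stats::sd(targets)
    if (scale == 0) stop("train_lbc: targets are degenerate (zero variance)")
    Y <- matrix((targets - center) / scale, ncol = 1)
  }

  set.seed(seed_stream(seed, "lbc_split"))
  n_val <- max(2L, round(config$val_fraction * n))
  val_ix <- sample.int(n, n_val)
  tr_ix <- setdiff(seq_len(n), val_ix)
  Ztr <- latents[tr_ix, , drop = FALSE]; Ytr <- Y[tr_ix, , drop = FALSE]
  Zv <- latents[val_ix, , drop = FALSE]; Yv <- Y[val_ix, , drop = FALSE]

  Fnet <- dense_net(c(d, config$f_hidden, K),
                    c(rep("elu", length(config$f_hidden)), "linear"),
                    seed = seed_stream(seed, "lbc_F"))
  Gnet <- dense_net(c(d, config$g_hidden, K),
                    c(rep("relu", length(config$g_hidden)), "softplus"),
                    seed = seed_stream(seed, "lbc_G"))
  pF <- net_params(Fnet); pG <- net_params(Gnet)
  oF <- adam_init(pF); oG <- adam_init(pG)
  tmp <- config$surrogate_temperature
  alpha <- config$alpha; tau <- config$tau
  bs <- min(config$batch_size, length(tr_ix))
  set.seed(seed_stream(seed, "lbc_train"))

  best_val <- Inf; best <- list(F = pF, G = pG); stall <- 0L
  log <- NULL
  for (round in seq_len(config$epochs)) {
    # --- phi-step: update G with F frozen ------------------------------------
    Fnet <- net_set_params(Fnet, pF)
    ord <- sample.int(nrow(Ztr))
    for (start in seq(1, nrow(Ztr), by = bs)) {
      ix <- ord[start:min(start + bs - 1L, nrow(Ztr))]
      Zb <- Ztr[ix, , drop = FALSE]; Yb <- Ytr[ix, , drop = FALSE]
      yh <- net_forward(Fnet, Zb)$out
      Gf <- net_forward(net_set_params(Gnet, pG), Zb)
      if (config$surrogate == "quantile") {
        # pinball gradient: the minimizer of the pinball loss on |y - y_hat|
        # is its alpha-quantile, i.e. exactly the hard-coverage optimum
        r <- abs(Yb - yh)
        dDelta <- ifelse(Gf$out < r, -alpha, 1 - alpha) / nrow(Zb)
      } else {
        sc <- smooth_coverage(yh, Gf$out, Yb, tmp)
        gap <- alpha - colMeans(sc$s)
        # d/d delta of sum_k |alpha - mean_i s_ik|
        dDelta <- sweep(sc$d_delta, 2, -sign(gap) / nrow(Zb), "*")
      }
      bw <- net_backward(net_set_params(Gnet, pG), Gf$cache, dDelta)
      st <- adam_step(pG, net_grads_flat(bw$grads), oG, config$lr)
      pG <- st$params; oG <- st$state
    }
    # --- theta-step: update F with G frozen ----------------------------------
    Gnet <- net_set_params(Gnet, pG)
    ord <- sample.int(nrow(Ztr))
    for (start in seq(1, nrow(Ztr), by = bs)) {
      ix <- ord[start:min(start + bs - 1L, nrow(Ztr))]
      Zb <- Ztr[ix, , drop = FALSE]; Yb <- Ytr[ix, , drop = FALSE]
      if (config$latent_noise > 0) {
        Zb <- Zb + matrix(stats::rnorm(length(Zb), sd = config$latent_noise),
                          nrow(Zb))
      }
      delta <- net_forward(Gnet, Zb)$out
      Ff <- net_forward(net_set_params(Fnet, pF), Zb)
      yh <- Ff$out
      dY <- ((yh - delta - Yb + tau) > 0) * 1 - ((Yb - yh - delta + tau) > 0) * 1
      dY <- dY / nrow(Zb)
      bw <- net_backward(net_set_params(Fnet, pF), Ff$cache, dY)
      st <- adam_step(pF, net_grads_flat(bw$grads), oF, config$lr)
      pF <- st$params; oF <- st$state
    }
    # --- validation score (calibration error + hinge) for convergence --------
    Fnet <- net_set_params(Fnet, pF); Gnet <- net_set_params(Gnet, pG)
    yhv <- net_forward(Fnet, Zv)$out
    dv <- net_forward(Gnet, Zv)$out
    vh <- hinge_interval_loss(yhv, dv, Yv, tau)
    vc <- interval_calibration_error(yhv, dv, Yv, alpha)
    log <- rbind(log, data.frame(round = round, val_hinge = vh, val_cal = vc,
                                 mean_delta = mean(dv)))
    if (vh + vc < best_val - 1e-6) {
      best_val <- vh + vc; best <- list(F = pF, G = pG); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  Fnet <- net_set_params(Fnet, best$F)
  Gnet <- net_set_params(Gnet, best$G)
  rownames(log) <- NULL
  structure(list(F_net = Fnet, G_net = Gnet, task = task, K = K,
                 class_levels = class_levels, center = center, scale = scale,
                 config = config, latent_dim = d, log = log),
            class = "lbc_model")
}

#' Interval predictions from a calibrated predictor
#'
#' @param object an [train_lbc()] model.
#' @param z latent vector or N x d matrix.
#' @param ... unused.
#' @return list with `y_hat` (N x K logits, or N x 1 on the original target
#'   scale for regression) and `delta` (N x K nonnegative half-widths); the
#'   prediction interval is `[y_hat - delta, y_hat + delta]`.
#' @export
predict.lbc_model <- function(object, z, ...) {
  single <- is.null(dim(z))
  z <- if (single) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(z) != object$latent_dim) stop("predict: latent dimension mismatch")
  yh <- net_forward(object$F_net, z)$out
  dl <- net_forward(object$G_net, z)$out
  if (object$task == "regression") {
    yh <- yh * object$scale + object$center
    dl <- dl * object$scale
  }
  list(y_hat = yh, delta = dl)
}

#' Class probabilities from a calibrated classifier
#'
#' Softmax of the predictor's logits.
#'
#' @param model a classification [train_lbc()] model (or any object with a
#'   `predict_logits` method).
#' @param z latent vector or N x d matrix.
#' @return N x K matrix of probabilities summing to one per row.
#' @export
class_probabilities <- function(model, z) {
  UseMethod("class_probabilities")
}

#' @export
class_probabilities.lbc_model <- function(model, z) {
  if (model$task != "classification") stop("class_probabilities: not a classifier")
  softmax(predict(model, z)$y_hat)
}

#' @export
print.lbc_model <- function(x, ...) {
  cat("lbc_model:", x$task,
      if (x$task == "classification") paste0("(K = ", x$K, ")") else "",
      "| alpha", x$config$alpha, "| tau", x$config$tau,
      "|", nrow(x$log), "alternation rounds\n")
  invisible(x)
}

#' Synthetic heteroscedastic regression task
#'
#' Draws latent-like inputs `z ~ N(0, I_d)` and responses
#' `y = w'z + s(z) * eps` with input-dependent noise scale
#' `s(z) = 0.1 + 0.5 * |z_1|`, the benchmark used to check that LbC's
#' held-out interval coverage matches the configured confidence level.
#'
#' @param n number of samples.
#' @param d input dimension (default 10).
#' @param seed integer seed.
#' @return list with `z` (n x d matrix), `y` (length-n response) and `w`.
#' @export
synthetic_interval_regression <- function(n, d = 10L, seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * d), n, d)
  w <- seq_len(d) / sqrt(sum(seq_len(d)^2))
  noise_sd <- 0.1 + 0.5 * abs(z[, 1])
  y <- drop(z %*% w) + rnorm(n, sd = noise_sd)
  list(z = z, y = y, w = w)
}

# hard-indicator coverage of held-out targets, the quantity calibration is
# judged on (fraction of targets inside [y_hat - delta, y_hat + delta],
# averaged over outputs)
interval_coverage <- function(model, z, targets) {
  pr <- predict(model, z)
  if (model$task == "classification") {
    lab <- if (is.factor(targets)) as.integer(targets) else as.integer(targets)
    Y <- labels_to_logits(lab, model$K, model$config$eps_negative)
  } else {
    Y <- matrix(targets, ncol = 1)
  }
  covered <- (Y >= pr$y_hat - pr$delta) & (Y <= pr$y_hat + pr$delta)
  mean(covered)
}
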