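# Wasserstein autoencoder: a strided convolutional encoder/decoder pair whose
# encoded distribution is pulled toward a standard-normal prior with an MMD
# penalty. The training loss is w1*MSE + w2*MMD + w3*(1 - SSIM) with the
# scheduled weights; counterfactual optimization and all predictors operate
# in the resulting latent space.

#' Configuration for the Wasserstein autoencoder
#'
#' Defaults reproduce the reference architecture: four 3x3 stride-2
#' convolutions with filters \[16, 32, 64, 32\], two fully connected encoder
#' layers (512, latent_dim), a mirrored decoder whose first fully connected
#' width is recomputed from the image geometry (6272 at 224x224, 512 at
#' 64x64), ReLU activations everywhere except the linear latent layer and the
#' sigmoid image output, Adam with initial learning rate 1e-3 divided by
#' 2/5/10 after epochs 30/50/100, and loss weights (MSE, MMD, SSIM) =
#' (1, 0.5, 0) for the first 20 epochs then (1, 0.1, 1).
#'
#' @param latent_dim latent dimensionality (default 100).
#' @param image_size input side length in pixels; must be divisible by 16
#'   (default 64, 224 supported).
#' @param conv_filters encoder filter counts per conv layer.
#' @param fc_width width of the fully connected layer adjoining the latent
#'   code on both sides (default 512).
#' @param epochs training epochs (default 150).
#' @param batch_size minibatch size (default 64).
#' @param lr initial Adam learning rate.
#' @param lr_milestones,lr_factors epochs after which `lr` is divided by the
#'   corresponding factor.
#' @param weights_early,weights_late loss weights (MSE, MMD, SSIM) before and
#'   after `weight_switch_epoch`.
#' @param weight_switch_epoch epoch at which the late weights take over.
#' @param kernel_scale IMQ kernel scale for the MMD term; default
#'   `2 * latent_dim`.
#' @return an object of class `wae_config`.
#' @export
wae_config <- function(latent_dim = 100L, image_size = 64L,
                       conv_filters = c(16L, 32L, 64L, 32L),
                       fc_width = 512L, epochs = 150L, batch_size = 64L,
                       lr = 1e-3, lr_milestones = c(30L, 50L, 100L),
                       lr_factors = c(2, 5, 10),
                       weights_early = c(1, 0.5, 0),
                       weights_late = c(1, 0.1, 1),
                       weight_switch_epoch = 20L,
                       kernel_scale = NULL) {
  if (image_size %% 16L != 0L) stop("image_size must be divisible by 16")
  if (any(c(weights_early, weights_late) < 0)) stop("loss weights must be nonnegative")
  stopifnot(latent_dim >= 2, epochs >= 1, batch_size >= 2,
            length(conv_filters) == 4, length(lr_milestones) == length(lr_factors))
  structure(list(
    latent_dim = as.integer(latent_dim), image_size = as.integer(image_size),
    conv_filters = as.integer(conv_filters), fc_width = as.integer(fc_width),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, lr_milestones = lr_milestones, lr_factors = lr_factors,
    weights_early = weights_early, weights_late = weights_late,
    weight_switch_epoch = as.integer(weight_switch_epoch),
    kernel_scale = kernel_scale %||% (2 * latent_dim)
  ), class = "wae_config")
}

init_wae <- function(config, seed = 1L) {
  S <- config$image_size
  cf <- config$conv_filters
  chans <- c(1L, cf)
  plans <- list(); sz <- S
  enc_conv <- vector("list", 4)
  for (l in 1:4) {
    plans[[l]] <- conv_plan(sz, sz)
    enc_conv[[l]] <- conv_layer(plans[[l]], chans[l], chans[l + 1],
                                seed = seed_stream(seed, paste0("enc_conv", l)))
    sz <- sz %/% 2L
  }
  feat <- sz * sz * cf[4]
  enc_fc <- dense_net(c(feat, config$fc_width, config$latent_dim),
                      c("relu", "linear"),
                      seed = seed_stream(seed, "enc_fc"))
  dec_geom <- sz * sz * 32L   # decoder re-enters the conv stack at 32 channels
  dec_fc <- dense_net(c(config$latent_dim, config$fc_width, dec_geom),
                      c("relu", "relu"),
                      seed = seed_stream(seed, "dec_fc"))
  dec_chans_in <- c(32L, 64L, 32L, 16L)
  dec_chans_out <- c(64L, 32L, 16L, 1L)
  dec_deconv <- vector("list", 4)
  dsz <- sz
  for (l in 1:4) {
    pl <- conv_plan(dsz * 2L, dsz * 2L)   # plan on the bigger output geometry
    dec_deconv[[l]] <- deconv_layer(pl, dec_chans_in[l], dec_chans_out[l],
                                    seed = seed_stream(seed, paste0("dec_deconv", l)))
    dsz <- dsz * 2L
  }
  structure(list(enc_conv = enc_conv, enc_fc = enc_fc, dec_fc = dec_fc,
                 dec_deconv = dec_deconv, config = config,
                 grid = sz, log = NULL),
            class = "wae_model")
}

# ---- forward / backward ------------------------------------------------------

wae_encode_fwd <- function(model, X) {   # X: (H, W, N)
  N <- dim(X)[3]
  h <- array(X, dim = c(dim(X)[1], dim(X)[2], 1L, N))
  conv_caches <- vector("list", 4)
  for (l in 1:4) {
    fw <- conv_forward(model$enc_conv[[l]], h)
    a <- fw$out
    h <- pmax(a, 0)
    conv_caches[[l]] <- list(fw = fw, a = a)
  }
  feat <- t(matrix(h, ncol = N))       # N x (s*s*C)
  fcf <- net_forward(model$enc_fc, feat)
  list(z = fcf$out, fc = fcf, conv = conv_caches, feat_dim = dim(h), N = N)
}

wae_encode_bwd <- function(model, cache, dZ) {
  bw <- net_backward(model$enc_fc, cache$fc$cache, dZ)
  grads_fc <- bw$grads
  dh <- array(t(bw$dX), dim = cache$feat_dim)
  grads_conv <- vector("list", 4)
  for (l in 4:1) {
    cc <- cache$conv[[l]]
    da <- dh * (cc$a > 0)
    cb <- conv_backward(model$enc_conv[[l]], cc$fw, da)
    grads_conv[[l]] <- list(dW = cb$dW, db = cb$db)
    dh <- cb$dX
  }
  list(fc = grads_fc, conv = grads_conv)
}

wae_decode_fwd <- function(model, Z) {   # Z: N x d
  N <- nrow(Z)
  fcf <- net_forward(model$dec_fc, Z)
  s <- model$grid
  h <- array(t(fcf$out), dim = c(s, s, 32L, N))
  caches <- vector("list", 4)
  for (l in 1:4) {
    fw <- deconv_forward(model$dec_deconv[[l]], h)
    a <- fw$out
    h <- if (l < 4) pmax(a, 0) else 1 / (1 + exp(-a))
    caches[[l]] <- list(fw = fw, a = a, h = h)
  }
  list(x = array(h, dim = c(dim(h)[1], dim(h)[2], N)), fc = fcf,
       deconv = caches, N = N)
}

wae_decode_bwd <- function(model, cache, dX) {
  N <- cache$N
  dh <- array(dX, dim = c(dim(dX)[1], dim(dX)[2], 1L, N))
  grads_deconv <- vector("list", 4)
  for (l in 4:1) {
    cc <- cache$deconv[[l]]
    da <- if (l < 4) dh * (cc$a > 0) else dh * cc$h * (1 - cc$h)
    db_ <- deconv_backward(model$dec_deconv[[l]], cc$fw, da)
    grads_deconv[[l]] <- list(dW = db_$dW, db = db_$db)
    dh <- db_$dX
  }
  s <- model$grid
  dfeat <- t(matrix(dh, ncol = N))
  bw <- net_backward(model$dec_fc, cache$fc$cache, dfeat)
  list(fc = bw$grads, deconv = grads_deconv, dZ = bw$dX)
}

wae_params <- function(model) {
  c(
    unlist(lapply(model$enc_conv, function(l) list(l$W, l$b)), recursive = FALSE),
    net_params(model$enc_fc),
    net_params(model$dec_fc),
    unlist(lapply(model$dec_deconv, function(l) list(l$W, l$b)), recursive = FALSE)
  )
}

wae_set_params <- function(model, params) {
  k <- 1L
  for (l in 1:4) {
    model$enc_conv[[l]]$W <- params[[k]]; k <- k + 1L
    model$enc_conv[[l]]$b <- params[[k]]; k <- k + 1L
  }
  nfc <- length(model$enc_fc$layers) * 2L
  model$enc_fc <- net_set_params(model$enc_fc, params[k:(k + nfc - 1L)]); k <- k + nfc
  ndc <- length(model$dec_fc$layers) * 2L
  model$dec_fc <- net_set_params(model$dec_fc, params[k:(k + ndc - 1L)]); k <- k + ndc
  for (l in 1:4) {
    model$dec_deconv[[l]]$W <- params[[k]]; k <- k + 1L
    model$dec_deconv[[l]]$b <- params[[k]]; k <- k + 1L
  }
  model
}

wae_grads_flat <- function(genc, gdec) {
  c(
    unlist(lapply(genc$conv, function(g) list(g$dW, g$db)), recursive = FALSE),
    net_grads_flat(genc$fc),
    net_grads_flat(gdec$fc),
    unlist(lapply(gdec$deconv, function(g) list(g$dW, g$db)), recursive = FALSE)
  )
}

# loss and gradients on one minibatch
wae_batch_loss <- function(model, Xb, prior, weights, Kh, Kw, want_grads = TRUE) {
  ef <- wae_encode_fwd(model, Xb)
  df <- wae_decode_fwd(model, ef$z)
  Xhat <- df$x
  np <- length(Xb)
  mse <- mean((Xhat - Xb)^2)
  mmd <- mmd_penalty(ef$z, prior, model$config$kernel_scale)
  sg <- if (weights[3] > 0 || !want_grads) {
    ssim_batch_grad(Xhat, Xb, Kh, Kw)
  } else list(value = NA_real_, grad = 0)
  total <- weights[1] * mse + weights[2] * mmd +
    weights[3] * (1 - if (is.na(sg$value)) 0 else sg$value)
  if (!want_grads) {
    return(list(mse = mse, mmd = mmd, ssim = sg$value, total = total))
  }
  dXhat <- weights[1] * 2 * (Xhat - Xb) / np
  if (weights[3] > 0) dXhat <- dXhat - weights[3] * sg$grad
  gdec <- wae_decode_bwd(model, df, dXhat)
  dZ <- gdec$dZ + weights[2] * mmd_grad(ef$z, prior, model$config$kernel_scale)
  genc <- wae_encode_bwd(model, ef, dZ)
  list(mse = mse, mmd = mmd, ssim = sg$value, total = total,
       grads = wae_grads_flat(genc, gdec))
}

#' Train the Wasserstein autoencoder
#'
#' Minimizes `w1*MSE + w2*MMD + w3*(1 - SSIM)` with Adam under the configured
#' weight and learning-rate schedules. Fresh prior samples are drawn per
#' minibatch; training is deterministic given the seed.
#'
#' @param dataset a [generate_dataset()] result, or an (H, W, N) array of
#'   images in \[0,1\].
#' @param config a [wae_config()]; its `image_size` must match the data.
#' @param seed integer seed controlling initialization, shuffling and prior
#'   draws.
#' @param verbose print per-epoch losses.
#' @return an object of class `wae_model` with a `log` data.frame
#'   (epoch, mse, mmd, ssim, total).
#' @export
train_wae <- function(dataset, config = wae_config(), seed = 1L, verbose = FALSE) {
  X <- if (inherits(dataset, "synthetic_dataset")) dataset$images else dataset
  if (is.null(dim(X)) || length(dim(X)) != 3 || dim(X)[3] < 1) {
    stop("train_wae: dataset must contain at least one image")
  }
  if (dim(X)[1] != config$image_size) {
    stop("train_wae: config image_size (", config$image_size,
         ") does not match data (", dim(X)[1], ")")
  }
  n <- dim(X)[3]
  model <- init_wae(config, seed)
  params <- wae_params(model)
  opt <- adam_init(params)
  Kh <- ssim_filter_matrix(config$image_size)
  Kw <- Kh
  set.seed(seed_stream(seed, "wae_train"))
  log <- NULL
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr
    for (j in seq_along(config$lr_milestones)) {
      if (epoch > config$lr_milestones[j]) lr <- config$lr / config$lr_factors[j]
    }
    w <- if (epoch <= config$weight_switch_epoch) config$weights_early else config$weights_late
    ord <- sample.int(n)
    bs <- min(config$batch_size, n)
    acc <- c(mse = 0, mmd = 0, ssim = 0, total = 0); nb <- 0L
    for (start in seq(1, n, by = bs)) {
      ix <- ord[start:min(start + bs - 1L, n)]
      if (length(ix) < 2) next
      Xb <- X[, , ix, drop = FALSE]
      prior <- matrix(rnorm(length(ix) * config$latent_dim), length(ix))
      model <- wae_set_params(model, params)
      bl <- wae_batch_loss(model, Xb, prior, w, Kh, Kw)
      st <- adam_step(params, bl$grads, opt, lr)
      params <- st$params; opt <- st$state
      acc <- acc + c(bl$mse, bl$mmd, if (is.na(bl$ssim)) 0 else bl$ssim, bl$total)
      nb <- nb + 1L
    }
    acc <- acc / nb
    log <- rbind(log, data.frame(epoch = epoch, mse = acc[1], mmd = acc[2],
                                 ssim = acc[3], total = acc[4]))
    if (verbose) {
      message(sprintf("epoch %3d  mse %.5f  mmd %.4f  ssim %.4f  total %.5f",
                      epoch, acc[1], acc[2], acc[3], acc[4]))
    }
  }
  model <- wae_set_params(model, params)
  rownames(log) <- NULL
  model$log <- log
  model
}

#' Encode images into the latent space
#'
#' Deterministic at inference and batch-consistent: encoding an image alone or
#' inside a batch gives the same code.
#'
#' @param model a trained [train_wae()] model.
#' @param x a single image matrix or an (H, W, N) array.
#' @return a latent vector (single image) or an N x latent_dim matrix.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "wae_model"))
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[1] != model$config$image_size || dim(x)[2] != model$config$image_size) {
    stop("encode: image shape does not match the model's image_size")
  }
  z <- wae_encode_fwd(model, x)$z
  if (single) drop(z) else z
}

#' Decode latent codes into images
#'
#' The decoder output passes through a saturating (sigmoid) nonlinearity, so
#' decoded images always lie in \[0,1\].
#'
#' @param model a trained [train_wae()] model.
#' @param z a latent vector or an N x latent_dim matrix.
#' @return an image matrix (single code) or an (H, W, N) array.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "wae_model"))
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$config$latent_dim) {
    stop("decode: latent dimension mismatch")
  }
  x <- wae_decode_fwd(model, z)$x
  if (single) x[, , 1] else x
}

# final hidden-layer activations of the encoder (the default feature space
# for the realism metric)
encoder_features <- function(model, x) {
  stopifnot(inherits(model, "wae_model"))
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(dim(x), 1L))
  ef <- wae_encode_fwd(model, x)
  feats <- ef$fc$cache[[1]]$h     # N x fc_width, post-ReLU
  if (single) drop(feats) else feats
}

#' @export
print.wae_model <- function(x, ...) {
  cfg <- x$config
  cat("wae_model: latent_dim", cfg$latent_dim, "| image", cfg$image_size, "x",
      cfg$image_size, "| filters", paste(cfg$conv_filters, collapse = ","), "\n")
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("trained %d epochs; final mse %.5f, mmd %.4f, ssim %.4f\n",
                nrow(x$log), last$mse, last$mmd, last$ssim))
  }
  invisible(x)
}

# decoder gradient w.r.t. z for a given upstream image gradient; used by
# analyses that need d image / d latent without exposing internals
decode_vjp <- function(model, z, dX) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  df <- wae_decode_fwd(model, z)
  if (length(dim(dX)) == 2) dX <- array(dX, dim = c(dim(dX), 1L))
  g <- wae_decode_bwd(model, df, dX)
  if (single) drop(g$dZ) else g$dZ
}
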