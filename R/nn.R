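# Minimal dense-network engine with manual backpropagation.
#
# All networks in the package (the WAE's fully connected blocks, the LbC
# predictor/interval pair, the baseline classifiers) are built from this
# representation: a list of layers, each holding a weight matrix W
# (d_in x d_out), a bias vector b and an activation name. Data flow uses
# row-major batches (n x d matrices) so every op maps onto BLAS matmuls.

ACTIVATIONS <- c("linear", "relu", "elu", "sigmoid", "softplus", "tanh")

act_forward <- function(a, act) {
  switch(act,
    linear   = a,
    relu     = pmax(a, 0),
    elu      = ifelse(a > 0, a, expm1(a)),
    sigmoid  = 1 / (1 + exp(-a)),
    softplus = ifelse(a > 30, a, log1p(exp(pmin(a, 30)))),
    tanh     = tanh(a),
    stop("unknown activation: ", act)
  )
}

# derivative expressed through the activation output h (and pre-activation a)
act_backward <- function(dh, h, a, act) {
  switch(act,
    linear   = dh,
    relu     = dh * (a > 0),
    elu      = dh * ifelse(a > 0, 1, h + 1),
    sigmoid  = dh * h * (1 - h),
    softplus = dh / (1 + exp(-a)),
    tanh     = dh * (1 - h^2),
    stop("unknown activation: ", act)
  )
}

#' Initialize a fully connected network
#'
#' @param sizes integer vector of layer widths, starting with the input
#'   dimension and ending with the output dimension.
#' @param activations character vector of per-layer activations (length
#'   `length(sizes) - 1`), or a single name recycled for all hidden layers
#'   with a linear output layer.
#' @param seed integer seed for the He-style weight initialization.
#' @return an object of class `dense_net`.
#' @keywords internal
dense_net <- function(sizes, activations = "relu", seed = 1L) {
  stopifnot(length(sizes) >= 2)
  n_layer <- length(sizes) - 1L
  if (length(activations) == 1L && n_layer > 1L) {
    activations <- c(rep(activations, n_layer - 1L), "linear")
  }
  stopifnot(length(activations) == n_layer, all(activations %in% ACTIVATIONS))
  set.seed(seed)
  layers <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    d_in <- sizes[l]; d_out <- sizes[l + 1L]
    sd <- sqrt(2 / d_in)
    layers[[l]] <- list(
      W = matrix(rnorm(d_in * d_out, sd = sd), d_in, d_out),
      b = numeric(d_out),
      act = activations[l]
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "dense_net")
}

# Forward pass. X: n x d_in matrix. dropout_masks: optional list of n x width
# 0/1 matrices applied after each hidden activation (inverted dropout is the
# caller's responsibility via the mask scale).
net_forward <- function(net, X, dropout_masks = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == net$sizes[1])
  n_layer <- length(net$layers)
  cache <- vector("list", n_layer)
  h <- X
  for (l in seq_len(n_layer)) {
    ly <- net$layers[[l]]
    a <- h %*% ly$W
    a <- sweep(a, 2, ly$b, "+")
    out <- act_forward(a, ly$act)
    if (!is.null(dropout_masks) && l < n_layer && !is.null(dropout_masks[[l]])) {
      out <- out * dropout_masks[[l]]
    }
    cache[[l]] <- list(input = h, a = a, h = out)
    h <- out
  }
  list(out = h, cache = cache)
}

# Backward pass: returns per-layer gradients and the gradient w.r.t. the input.
net_backward <- function(net, cache, dY, dropout_masks = NULL) {
  n_layer <- length(net$layers)
  grads <- vector("list", n_layer)
  dh <- dY
  for (l in rev(seq_len(n_layer))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (!is.null(dropout_masks) && l < n_layer && !is.null(dropout_masks[[l]])) {
      dh <- dh * dropout_masks[[l]]
    }
    da <- act_backward(dh, cc$h, cc$a, ly$act)
    grads[[l]] <- list(W = crossprod(cc$input, da), b = colSums(da))
    dh <- tcrossprod(da, ly$W)  # da %*% t(W)
  }
  list(grads = grads, dX = dh)
}

net_params <- function(net) {
  unlist(lapply(net$layers, function(l) list(l$W, l$b)), recursive = FALSE)
}

net_set_params <- function(net, params) {
  k <- 1L
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- params[[k]]; k <- k + 1L
    net$layers[[l]]$b <- params[[k]]; k <- k + 1L
  }
  net
}

net_grads_flat <- function(grads) {
  unlist(lapply(grads, function(g) list(g$W, g$b)), recursive = FALSE)
}

# ---- Adam optimizer over a flat list of parameter arrays --------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# softmax over rows, numerically stable
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
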