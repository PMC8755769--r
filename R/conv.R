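# Strided 3x3 convolution / transposed convolution via im2col gather/scatter.
#
# Images are arrays (H, W, C, N), column-major with H fastest. A conv "plan"
# precomputes, for every (output position, kernel offset) pair, the linear
# index of the contributing input pixel (0 for zero padding). Convolution is
# then a single BLAS matmul against a (k*k*C x F) weight matrix; the
# transposed convolution is its exact adjoint (scatter-add), so the same plan
# drives both directions and both backward passes.

conv_plan <- function(H, W, k = 3L, stride = 2L, pad = 1L) {
  oh <- (H + 2L * pad - k) %/% stride + 1L
  ow <- (W + 2L * pad - k) %/% stride + 1L
  oi <- rep(seq_len(oh), times = ow)           # output row, fastest
  oj <- rep(seq_len(ow), each = oh)
  P <- oh * ow
  idx <- integer(P * k * k)
  pos <- 1L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      ii <- stride * (oi - 1L) + ki - pad      # input row per output position
      jj <- stride * (oj - 1L) + kj - pad
      valid <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      lin <- ifelse(valid, (jj - 1L) * H + ii, 0L)
      idx[seq.int(pos, pos + P - 1L)] <- lin
      pos <- pos + P
    }
  }
  list(H = H, W = W, k = k, stride = stride, pad = pad,
       oh = oh, ow = ow, P = P, idx = idx)
}

# gather patches: X (H,W,C,N) -> matrix (P*N, k*k*C)
im2col_gather <- function(X, plan) {
  d <- dim(X); C <- d[3]; N <- d[4]
  kk <- plan$k * plan$k; P <- plan$P
  dim(X) <- c(d[1] * d[2], C * N)
  Xpad <- rbind(0, X)
  Xg <- Xpad[plan$idx + 1L, , drop = FALSE]    # (P*kk, C*N)
  dim(Xg) <- c(P, kk, C, N)
  Xg <- aperm(Xg, c(1, 4, 2, 3))               # (P, N, kk, C)
  dim(Xg) <- c(P * N, kk * C)
  Xg
}

# exact adjoint of im2col_gather: M (P*N, k*k*C) -> array (H,W,C,N)
col2im_scatter <- function(M, plan, C, N) {
  kk <- plan$k * plan$k; P <- plan$P
  dim(M) <- c(P, N, kk, C)
  M <- aperm(M, c(1, 3, 4, 2))                 # (P, kk, C, N)
  dim(M) <- c(P * kk, C * N)
  rs <- rowsum(M, group = plan$idx)            # sums rows sharing a target pixel
  out <- matrix(0, plan$H * plan$W + 1L, C * N)
  out[as.integer(rownames(rs)) + 1L, ] <- rs
  out <- out[-1L, , drop = FALSE]              # drop the zero-pad bucket
  dim(out) <- c(plan$H, plan$W, C, N)
  out
}

# reshape between (oh,ow,F,N) arrays and (P*N, F) matrices
out_arr2mat <- function(Y, plan) {
  d <- dim(Y); F <- d[3]; N <- d[4]
  dim(Y) <- c(plan$P, F, N)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(plan$P * N, F)
  Y
}

out_mat2arr <- function(M, plan, F, N) {
  dim(M) <- c(plan$P, N, F)
  M <- aperm(M, c(1, 3, 2))
  dim(M) <- c(plan$oh, plan$ow, F, N)
  M
}

# ---- layers ------------------------------------------------------------------
# A conv layer maps (H,W,Cin,N) -> (oh,ow,F,N); W has dim (k*k*Cin, F).
# A deconv layer is the adjoint map (oh,ow,Cs,N) -> (H,W,Cb,N); its weight is
# stored in the conv orientation (k*k*Cb, Cs) so adjointness is structural.

conv_layer <- function(plan, c_in, c_out, seed) {
  set.seed(seed)
  fan_in <- plan$k * plan$k * c_in
  list(type = "conv", plan = plan, c_in = c_in, c_out = c_out,
       W = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = numeric(c_out))
}

deconv_layer <- function(plan, c_small, c_big, seed) {
  set.seed(seed)
  fan_in <- plan$k * plan$k * c_big
  list(type = "deconv", plan = plan, c_in = c_small, c_out = c_big,
       W = matrix(rnorm(fan_in * c_small, sd = sqrt(2 / (plan$k * plan$k * c_small))),
                  fan_in, c_small),
       b = numeric(c_big))
}

conv_forward <- function(layer, X) {
  N <- dim(X)[4]
  Xg <- im2col_gather(X, layer$plan)
  Ym <- Xg %*% layer$W
  Ym <- sweep(Ym, 2, layer$b, "+")
  list(out = out_mat2arr(Ym, layer$plan, layer$c_out, N), Xg = Xg, N = N)
}

conv_backward <- function(layer, cache, dY) {
  dYm <- out_arr2mat(dY, layer$plan)
  dW <- crossprod(cache$Xg, dYm)
  db <- colSums(dYm)
  dX <- col2im_scatter(tcrossprod(dYm, layer$W), layer$plan, layer$c_in, cache$N)
  list(dW = dW, db = db, dX = dX)
}

deconv_forward <- function(layer, X) {
  N <- dim(X)[4]
  Xm <- out_arr2mat(X, layer$plan)                        # (P*N, Cs)
  Yb <- col2im_scatter(tcrossprod(Xm, layer$W), layer$plan, layer$c_out, N)
  Yb <- sweep(Yb, 3, layer$b, "+")
  list(out = Yb, Xm = Xm, N = N)
}

deconv_backward <- function(layer, cache, dY) {
  dYg <- im2col_gather(dY, layer$plan)                    # (P*N, kk*Cb)
  dX <- out_mat2arr(dYg %*% layer$W, layer$plan, layer$c_in, cache$N)
  dW <- crossprod(dYg, cache$Xm)
  db <- colSums(matrix(aperm(dY, c(1, 2, 4, 3)),
                       ncol = layer$c_out))               # sum over H,W,N
  list(dW = dW, db = db, dX = dX)
}
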