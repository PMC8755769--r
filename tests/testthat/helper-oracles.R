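# independent brute-force implementations of the metric kernels, used as
# oracles by both the unit tests and the oracle-equivalence acceptance check

validity_oracle <- function(pred, targ, mode) {
  if (mode == "categorical") {
    sum(pred == targ) / length(pred)
  } else {
    mean(abs(targ - pred) / abs(targ))
  }
}

sparsity_oracle <- function(x, xb, eps) {
  n <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    if (abs(x[i, j] - xb[i, j]) > eps) n <- n + 1
  }
  n / length(x)
}

proximity_oracle <- function(zb, train, K) {
  d <- apply(train, 1, function(r) sqrt(sum((r - zb)^2)))
  mean(sort(d)[seq_len(K)])
}

realism_oracle <- function(g, real, K) {
  best <- -Inf
  for (j in seq_len(nrow(real))) {
    d_others <- sort(apply(real[-j, , drop = FALSE], 1,
                           function(r) sqrt(sum((r - real[j, ])^2))))
    r_j <- d_others[K] / sqrt(sum((real[j, ] - g)^2))
    if (r_j > best) best <- r_j
  }
  best
}
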