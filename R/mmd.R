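# Maximum mean discrepancy between latent codes and prior samples, the
# divergence that pulls the WAE's encoded distribution toward the standard
# normal prior. Inverse-multiquadratic kernel k(x, y) = C / (C + ||x - y||^2)
# with C = 2 * latent_dim by default (the standard WAE-MMD choice: bounded
# gradients, heavy tails).

imq_cross <- function(X, Y, C) {
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sq[sq < 0] <- 0
  C / (C + sq)
}

#' Unbiased squared maximum mean discrepancy
#'
#' Two-sample unbiased MMD^2 estimate with an inverse-multiquadratic kernel,
#' used as the latent prior-matching term of the Wasserstein autoencoder.
#' Being unbiased, the estimate can be slightly negative when the two samples
#' come from the same distribution.
#'
#' @param codes matrix (n x d) of latent codes, one row per sample.
#' @param prior_samples matrix (m x d) of draws from the prior.
#' @param kernel_scale kernel bandwidth C; defaults to `2 * d`.
#' @return a scalar, symmetric in its two arguments.
#' @export
mmd_penalty <- function(codes, prior_samples, kernel_scale = NULL) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  if (is.null(dim(prior_samples))) prior_samples <- matrix(prior_samples, nrow = 1)
  if (ncol(codes) != ncol(prior_samples)) {
    stop("mmd_penalty: dimension mismatch (", ncol(codes), " vs ",
         ncol(prior_samples), ")")
  }
  if (nrow(codes) < 1 || nrow(prior_samples) < 1) stop("mmd_penalty: empty sample set")
  if (is.null(kernel_scale)) kernel_scale <- 2 * ncol(codes)
  n <- nrow(codes); m <- nrow(prior_samples)
  Kxx <- imq_cross(codes, codes, kernel_scale)
  Kyy <- imq_cross(prior_samples, prior_samples, kernel_scale)
  Kxy <- imq_cross(codes, prior_samples, kernel_scale)
  t1 <- if (n > 1) (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) else 0
  t2 <- if (m > 1) (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) else 0
  t1 + t2 - 2 * mean(Kxy)
}

# gradient of mmd_penalty w.r.t. codes (Z). Returns n x d matrix.
mmd_grad <- function(Z, Y, C) {
  n <- nrow(Z); m <- nrow(Y)
  # d k / d z_i for k = C/(C + r^2): -2 C (z_i - z_j) / (C + r^2)^2
  Kxx <- imq_cross(Z, Z, C)
  Wxx <- -2 * Kxx^2 / C
  diag(Wxx) <- 0
  if (n > 1) {
    Gxx <- (Z * rowSums(Wxx) - Wxx %*% Z) * (2 / (n * (n - 1)))
  } else Gxx <- 0 * Z
  Kxy <- imq_cross(Z, Y, C)
  Wxy <- -2 * Kxy^2 / C
  Gxy <- (Z * rowSums(Wxy) - Wxy %*% Y) * (-2 / (n * m))
  Gxx + Gxy
}
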