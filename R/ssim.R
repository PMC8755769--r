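# Structural similarity (SSIM) with an 11-pixel Gaussian window, plus the
# analytic gradient needed to use (1 - SSIM) as a training loss.
#
# Statistics are computed on 'valid' windows only (no padding), the
# convention of the original SSIM formulation, so the similarity map has
# size (H-10) x (W-10) and the score is its mean.

ssim_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# 'valid' 1-D Gaussian filter along rows as a banded matrix (H-size+1) x H
ssim_filter_matrix <- function(H, size = 11L, sigma = 1.5) {
  w <- ssim_window(size, sigma)
  Hs <- H - size + 1L
  K <- matrix(0, Hs, H)
  for (i in seq_len(Hs)) K[i, i:(i + size - 1L)] <- w
  K
}

# separable valid blur of a stack (H, W, N) -> (H', W', N)
ssim_blur <- function(X, Kh, Kw) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]
  dim(X) <- c(H, W * N)
  A <- Kh %*% X                                    # (H', W*N)
  Hs <- nrow(Kh)
  dim(A) <- c(Hs, W, N)
  A <- aperm(A, c(2, 1, 3)); dim(A) <- c(W, Hs * N)
  B <- Kw %*% A                                    # (W', H'*N)
  Ws <- nrow(Kw)
  dim(B) <- c(Ws, Hs, N)
  aperm(B, c(2, 1, 3))
}

# adjoint of ssim_blur: (H', W', N) -> (H, W, N)
ssim_blur_t <- function(G, Kh, Kw) {
  d <- dim(G); Hs <- d[1]; Ws <- d[2]; N <- d[3]
  G <- aperm(G, c(2, 1, 3)); dim(G) <- c(Ws, Hs * N)
  A <- crossprod(Kw, G)                            # (W, H'*N)
  W <- ncol(Kw)
  dim(A) <- c(W, Hs, N)
  A <- aperm(A, c(2, 1, 3)); dim(A) <- c(Hs, W * N)
  B <- crossprod(Kh, A)                            # (H, W*N)
  H <- ncol(Kh)
  dim(B) <- c(H, W, N)
  B
}

ssim_stats <- function(A, B, Kh, Kw, C1, C2) {
  mx <- ssim_blur(A, Kh, Kw); my <- ssim_blur(B, Kh, Kw)
  u <- ssim_blur(A * A, Kh, Kw); uy <- ssim_blur(B * B, Kh, Kw)
  v <- ssim_blur(A * B, Kh, Kw)
  sx2 <- u - mx^2; sy2 <- uy - my^2; sxy <- v - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- sx2 + sy2 + C2
  list(mx = mx, my = my, u = u, v = v, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = (A1 * A2) / (B1 * B2))
}

#' Structural similarity between two images
#'
#' Computes the mean SSIM index over all fully valid 11x11 Gaussian-weighted
#' windows (sigma 1.5), the standard single-scale formulation for images with
#' intensities in \[0,1\].
#'
#' @param a,b numeric matrices of identical dimensions (grayscale images,
#'   intensities in \[0,1\]).
#' @param window window width in pixels (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return a scalar in \[-1, 1\]; 1 iff the images are identical.
#' @export
#' @examples
#' x <- matrix(runif(24^2), 24)
#' ssim(x, x)  # 1
ssim <- function(a, b, window = 11L, sigma = 1.5) {
  if (!identical(dim(a), dim(b))) stop("ssim: images must have the same shape")
  if (nrow(a) < window || ncol(a) < window) {
    stop("ssim: images smaller than the ", window, "-pixel window")
  }
  Kh <- ssim_filter_matrix(nrow(a), window, sigma)
  Kw <- ssim_filter_matrix(ncol(a), window, sigma)
  C1 <- 0.01^2; C2 <- 0.03^2
  st <- ssim_stats(array(a, c(dim(a), 1)), array(b, c(dim(b), 1)), Kh, Kw, C1, C2)
  mean(st$S)
}

# Batch mean SSIM and its gradient w.r.t. the first stack (the
# reconstruction). A, B: (H, W, N). Returns list(value, grad).
ssim_batch_grad <- function(A, B, Kh, Kw) {
  C1 <- 0.01^2; C2 <- 0.03^2
  st <- ssim_stats(A, B, Kh, Kw, C1, C2)
  np <- length(st$S)
  D <- st$B1 * st$B2
  # dS w.r.t. the filtered quantities mx, u, v (my, uy fixed)
  dS <- array(1 / np, dim = dim(st$S))
  g_m <- dS * ((st$A2 * 2 * st$my + st$A1 * (-2 * st$my)) / D -
                 st$S * (2 * st$mx / st$B1 - 2 * st$mx / st$B2))
  g_u <- dS * (-st$S / st$B2)
  g_v <- dS * (2 * st$A1 / D)
  grad <- ssim_blur_t(g_m, Kh, Kw) +
    2 * A * ssim_blur_t(g_u, Kh, Kw) +
    B * ssim_blur_t(g_v, Kh, Kw)
  list(value = mean(st$S), grad = grad)
}
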