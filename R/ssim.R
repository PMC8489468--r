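# Structural similarity index with a Gaussian sliding window, plus the
# analytic gradient used when SSIM enters the training loss.

gaussian_kernel_1d <- function(win_size, sigma) {
  h <- (win_size - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# shrink the window to the largest odd size that fits the image
effective_win <- function(dims, win_size) {
  w <- min(win_size, dims)
  if (w %% 2 == 0) w <- w - 1L
  if (w < 3) stop("image too small for SSIM (needs >= 3 pixels per side)")
  as.integer(w)
}

ssim_stats <- function(x, y, win_size, sigma, K1, K2, data_range) {
  k <- gaussian_kernel_1d(win_size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mux <- cpp_sep_corr_valid(x, k)
  muy <- cpp_sep_corr_valid(y, k)
  sx2 <- cpp_sep_corr_valid(x * x, k) - mux^2
  sy2 <- cpp_sep_corr_valid(y * y, k) - muy^2
  sxy <- cpp_sep_corr_valid(x * y, k) - mux * muy
  A1 <- 2 * mux * muy + C1
  A2 <- 2 * sxy + C2
  B1 <- mux^2 + muy^2 + C1
  B2 <- sx2 + sy2 + C2
  list(k = k, mux = mux, muy = muy, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = (A1 * A2) / (B1 * B2))
}

#' Structural similarity index (SSIM)
#'
#' Gaussian-window SSIM (window 11, sigma 1.5, K1 = 0.01, K2 = 0.03 by
#' default) averaged over all fully interior windows (borders of half the
#' window width are cropped). For images smaller than the window, the window
#' shrinks to the largest odd size that fits.
#'
#' @param x,y numeric matrices of equal shape.
#' @param data_range dynamic range of the data (1.0 for normalized images).
#' @param win_size odd Gaussian window size.
#' @param sigma Gaussian window standard deviation, pixels.
#' @param K1,K2 stabilization constants.
#' @return scalar mean SSIM.
#' @export
ssim <- function(x, y, data_range = 1.0, win_size = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            data_range > 0)
  w <- effective_win(min(dim(x)), win_size)
  st <- ssim_stats(x, y, w, sigma, K1, K2, data_range)
  mean(st$S)
}

# gradient of mean SSIM(x, y) with respect to x; chain rule through the
# valid-window Gaussian filtering (adjoint = full convolution)
ssim_grad <- function(x, y, data_range = 1.0, win_size = 11L, sigma = 1.5,
                      K1 = 0.01, K2 = 0.03) {
  w <- effective_win(min(dim(x)), win_size)
  st <- ssim_stats(x, y, w, sigma, K1, K2, data_range)
  N <- length(st$S)
  dS_dmux <- 2 * st$muy * st$A2 / (st$B1 * st$B2) -
    2 * st$mux * st$S / st$B1
  dS_dsx2 <- -st$S / st$B2
  dS_dsxy <- 2 * st$A1 / (st$B1 * st$B2)
  term_mu <- cpp_sep_conv_full(dS_dmux - 2 * st$mux * dS_dsx2 -
                                 st$muy * dS_dsxy, st$k)
  term_x <- cpp_sep_conv_full(dS_dsx2, st$k)
  term_y <- cpp_sep_conv_full(dS_dsxy, st$k)
  (term_mu + 2 * x * term_x + y * term_y) / N
}
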