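#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` between a reference and a test image.
#' Identical images have zero mean-squared error; this is reported as the
#' distinguished sentinel `Inf` rather than raised as an error, because
#' identical-image comparisons legitimately occur (e.g. full sampling).
#'
#' @param reference,test numeric matrices of equal shape.
#' @param data_range dynamic range of the data (default 1, images normalized).
#' @return PSNR in decibels (`Inf` if the images are identical).
#' @examples
#' a <- matrix(0.5, 8, 8)
#' psnr(a, a + 1 / 255) # 20*log10(255) = 48.13 dB
#' @export
psnr <- function(reference, test, data_range = 1) {
  assert_image(reference, "reference"); assert_image(test, "test")
  if (!all(dim(reference) == dim(test))) stop_dim("psnr: shape mismatch")
  if (data_range <= 0) stop_invalid("psnr: data_range must be positive")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM in the standard stabilized form: local means, variances
#' and covariance are estimated under a sliding Gaussian window (11 x 11,
#' sigma 1.5 by default) and combined as
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2} and \eqn{L} the data
#' range. The map is averaged over all fully-interior window positions.
#' The function is exactly symmetric in its two arguments.
#'
#' @inheritParams psnr
#' @param window_size odd window side in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param K1,K2 stabilization constants.
#' @return SSIM in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(reference, test, data_range = 1, window_size = 11,
                 sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  assert_image(reference, "reference"); assert_image(test, "test")
  if (!all(dim(reference) == dim(test))) stop_dim("ssim: shape mismatch")
  if (any(dim(reference) < window_size))
    stop_invalid("ssim: image smaller than the local window")
  g <- gaussian_kernel1d(window_size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  f <- function(z) conv2_valid_sep(z, g)
  mu1 <- f(reference); mu2 <- f(test)
  s11 <- f(reference * reference) - mu1 * mu1
  s22 <- f(test * test) - mu2 * mu2
  s12 <- f(reference * test) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' @noRd
gaussian_kernel1d <- function(size, sigma) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  g / sum(g)
}

#' valid-region convolution with a separable symmetric 1-D kernel applied
#' along both axes
#' @noRd
conv2_valid_sep <- function(z, g) {
  k <- length(g)
  h <- (k - 1) / 2
  zc <- stats::filter(z, g, sides = 2)
  zc <- zc[(h + 1):(nrow(z) - h), , drop = FALSE]
  zr <- t(stats::filter(t(zc), g, sides = 2))
  matrix(zr[, (h + 1):(ncol(z) - h), drop = FALSE],
         nrow(z) - 2 * h, ncol(z) - 2 * h)
}

#' Quality report for a reconstruction
#'
#' Bundles PSNR and SSIM against a reference with bookkeeping labels, the
#' unit in which benchmark tables are assembled.
#'
#' @inheritParams psnr
#' @param method_label text label of the reconstruction method.
#' @param sampling_rate k-space sampling fraction the test image was made at.
#' @return a one-row `data.frame` with columns `method`, `sampling_rate`,
#'   `psnr_db`, `ssim`.
#' @export
quality_report <- function(reference, test, method_label = "",
                           sampling_rate = NA_real_, data_range = 1) {
  data.frame(method = method_label, sampling_rate = sampling_rate,
             psnr_db = psnr(reference, test, data_range),
             ssim = ssim(reference, test, data_range),
             stringsAsFactors = FALSE)
}
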