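#' Spatial-domain intensity enhancement
#'
#' Applies a monotone point transform `U` to the pixel intensities
#' (`g = U(f)`). Only named monotone maps are supported -- gamma
#' correction, linear min--max stretch, and histogram equalization -- so
#' every admissible transform is order-preserving on `[0, 1]` and the
#' output stays in `[0, 1]`.
#'
#' @param image real image matrix with values in `[0, 1]`.
#' @param transform `"gamma"`, `"stretch"` or `"histeq"`.
#' @param gamma exponent for the gamma map (`out = in^gamma`), > 0.
#' @return enhanced image, same shape, values in `[0, 1]`.
#' @export
enhance_spatial <- function(image, transform = c("gamma", "stretch", "histeq"),
                            gamma = 1) {
  assert_image(image)
  transform <- match.arg(transform)
  if (transform == "gamma") {
    if (!is.numeric(gamma) || gamma <= 0)
      stop_invalid("gamma must be positive (monotone map)")
    return(clip01(image)^gamma)
  }
  if (transform == "stretch") {
    lo <- min(image); hi <- max(image)
    if (hi - lo < .Machine$double.eps) return(matrix(0, nrow(image), ncol(image)))
    return((image - lo) / (hi - lo))
  }
  # histogram equalization via the empirical cdf (a monotone map)
  cdf <- stats::ecdf(as.vector(image))
  out <- matrix(cdf(as.vector(image)), nrow(image), ncol(image))
  clip01(out)
}

#' Frequency-domain enhancement
#'
#' Transforms the image to k-space with the centered unitary transform,
#' multiplies by a radially symmetric nonnegative gain profile, transforms
#' back, takes the real part, and clips to `[0, 1]`. Supported profiles:
#'
#' * `"gaussian_high_boost"`: `gain = 1 + boost * (1 - exp(-r^2 / (2 s^2)))`
#'   -- unity at DC, amplifying high frequencies by up to `1 + boost`;
#' * `"butterworth_highpass"`: `gain = offset + (1 - offset) / (1 + (cutoff/r)^(2n))`
#'   -- a high-pass with a DC floor of `offset` so the mean is retained.
#'
#' @param image real image matrix.
#' @param filter_spec list with `profile` and its parameters (`boost`,
#'   `sigma` for the Gaussian; `cutoff`, `order`, `offset` for the
#'   Butterworth). All gains must be nonnegative.
#' @return enhanced image, same shape.
#' @export
enhance_frequency <- function(image,
                              filter_spec = list(profile = "gaussian_high_boost",
                                                 boost = 1, sigma = 0.25)) {
  assert_image(image)
  gain <- frequency_gain(dim(image), filter_spec)
  if (any(gain < 0)) stop_invalid("negative gains are not allowed")
  out <- Re(ifft2c(fft2c(image) * gain))
  clip01(out)
}

#' @noRd
frequency_gain <- function(shape, spec) {
  H <- shape[1]; W <- shape[2]
  dc <- dc_index(shape)
  ry <- (seq_len(H) - dc[1]) / (H / 2)
  rx <- (seq_len(W) - dc[2]) / (W / 2)
  r <- sqrt(outer(ry^2, rx^2, `+`)) # normalized radius, 0 at DC
  profile <- spec$profile %||% "gaussian_high_boost"
  if (profile == "gaussian_high_boost") {
    boost <- spec$boost %||% 1
    s <- spec$sigma %||% 0.25
    if (boost < -1) stop_invalid("negative gains are not allowed")
    1 + boost * (1 - exp(-r^2 / (2 * s^2)))
  } else if (profile == "butterworth_highpass") {
    cutoff <- spec$cutoff %||% 0.3
    n <- spec$order %||% 2
    offset <- spec$offset %||% 0.2
    if (offset < 0) stop_invalid("negative gains are not allowed")
    g <- offset + (1 - offset) / (1 + (cutoff / pmax(r, 1e-12))^(2 * n))
    g[r == 0] <- offset
    g
  } else if (profile == "flat") {
    matrix(spec$gain %||% 1, H, W)
  } else if (profile == "dc_only") {
    g <- matrix(0, H, W); g[dc[1], dc[2]] <- 1; g
  } else stop_invalid("unknown frequency gain profile: ", profile)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
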