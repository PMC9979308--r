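#' Centered unitary 2-D Fourier operators
#'
#' `fft2c()` and `ifft2c()` realize the forward and inverse 2-D discrete
#' Fourier transform used throughout the reconstruction code: both are
#' *centered* (the zero-frequency coefficient sits at
#' `(floor(H/2)+1, floor(W/2)+1)`) and *unitary* (norm-preserving, so
#' Parseval holds exactly and `ifft2c(fft2c(x))` returns `x` to machine
#' precision).
#'
#' @param x a 2-D numeric or complex matrix.
#' @return a complex matrix of the same shape.
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) {
  if (!is.matrix(x)) stop_dim("fft2c expects a 2-D matrix")
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  if (!is.matrix(x)) stop_dim("ifft2c expects a 2-D matrix")
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' @noRd
fftshift2 <- function(x) {
  d <- dim(x)
  roll2(x, floor(d[1] / 2), floor(d[2] / 2))
}

#' @noRd
ifftshift2 <- function(x) {
  d <- dim(x)
  roll2(x, ceiling(d[1] / 2), ceiling(d[2] / 2))
}

#' @noRd
roll2 <- function(x, r, c) {
  d <- dim(x)
  if (r %% d[1] != 0) {
    i <- seq_len(d[1])
    x <- x[c(i[(d[1] - r + 1):d[1]], i[1:(d[1] - r)]), , drop = FALSE]
  }
  if (c %% d[2] != 0) {
    j <- seq_len(d[2])
    x <- x[, c(j[(d[2] - c + 1):d[2]], j[1:(d[2] - c)]), drop = FALSE]
  }
  x
}

#' Index of the zero-frequency (DC) coefficient of the centered transform
#' @param shape integer vector `(rows, cols)`.
#' @return integer vector `(row, col)`, 1-based.
#' @export
dc_index <- function(shape) c(floor(shape[1] / 2) + 1L, floor(shape[2] / 2) + 1L)

#' Zero-filled reconstruction
#'
#' Inverse centered transform of undersampled k-space with missing entries
#' left at zero -- the baseline every reconstruction method must beat.
#'
#' @param sample a [kspace_sample] record.
#' @return a real image matrix (real part of the inverse transform, clipped
#'   to `[0, 1]`).
#' @export
zero_filled <- function(sample) {
  stopifnot(inherits(sample, "kspace_sample"))
  clip01(Re(ifft2c(sample$data)))
}

#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)
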