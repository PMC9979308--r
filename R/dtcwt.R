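#' Dual-tree complex wavelet denoising
#'
#' The transform maintains two real wavelet trees whose wavelets form an
#' approximate Hilbert pair, so that the paired coefficients behave like the
#' real and imaginary parts of a complex, near-analytic wavelet: magnitudes
#' are nearly shift invariant and directionally selective, which makes
#' magnitude thresholding a markedly better denoiser than thresholding a
#' single decimated wavelet tree.
#'
#' Both trees use a single length-14 orthonormal lowpass filter whose group
#' delay is a quarter sample off center (6.25 samples): tree B takes the
#' time-reversed filter at levels >= 2 (delay 6.75, i.e. the required
#' half-sample offset) and the one-sample-shifted filter at level 1. The
#' filter was designed by paraunitary-lattice optimization of stopband
#' energy and passband phase linearity; the resulting complex wavelet has
#' about -35 dB of negative-frequency leakage. Orthonormality makes each
#' tree perfectly reconstructing, so the full transform (the average of the
#' four row/column tree combinations) is an exact inverse when no
#' thresholding is applied.
#'
#' @name dtcwt
NULL

# length-14 orthonormal quarter-delay lowpass (see package vignette);
# orthonormal to 1e-16, sum sqrt(2), group delay ~6.25 samples.
QSHIFT14 <- c( 0.00074876731361477, -0.00080493648583442,
               0.04011837621661538, -0.04080519327251398,
              -0.12315815252859956,  0.28847380504981790,
               0.74423101529841110,  0.57259901729887910,
               0.01976254378065457, -0.12250141330262374,
               0.03042845954092321,  0.01481913527800239,
              -0.00502422843507174, -0.00467363337917999)

#' Specify the wavelet shrinkage
#'
#' @param levels number of decomposition levels (>= 1).
#' @param threshold nonnegative magnitude threshold applied to the complex
#'   highpass coefficients (same units as image intensity).
#' @param threshold_mode `"soft"` (shrink toward zero) or `"hard"` (keep or
#'   kill).
#' @return an object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(levels = 3, threshold = 0,
                         threshold_mode = c("soft", "hard")) {
  threshold_mode <- match.arg(threshold_mode)
  if (levels < 1) stop_invalid("levels must be >= 1")
  if (threshold < 0) stop_invalid("threshold must be >= 0")
  structure(list(levels = as.integer(levels), threshold = threshold,
                 threshold_mode = threshold_mode), class = "wavelet_spec")
}

#' Denoise an image by dual-tree complex wavelet magnitude thresholding
#'
#' @param image real image matrix.
#' @param spec a [wavelet_spec].
#' @return the denoised image, same shape as the input. With
#'   `threshold = 0` the output equals the input to machine precision.
#' @export
dtcwt_denoise <- function(image, spec) {
  assert_image(image)
  stopifnot(inherits(spec, "wavelet_spec"))
  d <- dim(image)
  block <- 2^spec$levels
  pd <- ceiling(d / block) * block
  # the coarsest level must still be longer than the 14/15-tap filters
  if (min(pd) / 2^(spec$levels - 1) < 16)
    stop_invalid("too many levels for this image size")
  x <- reflect_pad(image, pd[1] - d[1], pd[2] - d[2])
  dec <- dtcwt_fwd(x, spec$levels)
  if (spec$threshold > 0)
    dec <- dtcwt_threshold(dec, spec$threshold, spec$threshold_mode)
  out <- dtcwt_inv(dec)
  out[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

## ---- internal machinery -------------------------------------------------

#' @noRd
reflect_pad <- function(x, pr, pc) {
  if (pr > 0) x <- rbind(x, x[nrow(x) - seq_len(pr) + 1, , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, ncol(x) - seq_len(pc) + 1, drop = FALSE])
  x
}

#' quadrature-mirror highpass of an even-length orthonormal lowpass
#' @noRd
qmf_high <- function(h) ((-1)^(seq_along(h) - 1)) * rev(h)

#' circular cross-correlation of each column of X with filter h
#' @noRd
circ_corr_cols <- function(X, h) {
  N <- nrow(X)
  Hf <- stats::fft(c(h, rep(0, N - length(h))))
  Re(stats::mvfft(stats::mvfft(X) * Conj(Hf), inverse = TRUE)) / N
}

#' circular convolution of each column of X with filter h
#' @noRd
circ_conv_cols <- function(X, h) {
  N <- nrow(X)
  Hf <- stats::fft(c(h, rep(0, N - length(h))))
  Re(stats::mvfft(stats::mvfft(X) * Hf, inverse = TRUE)) / N
}

#' one level of 1-D analysis along columns: returns list(lo, hi), half height
#' @noRd
afb_cols <- function(X, fb) {
  keep <- seq(1, nrow(X), by = 2)
  list(lo = circ_corr_cols(X, fb$h)[keep, , drop = FALSE],
       hi = circ_corr_cols(X, fb$g)[keep, , drop = FALSE])
}

#' inverse of `afb_cols`
#' @noRd
sfb_cols <- function(lo, hi, fb) {
  N <- 2 * nrow(lo)
  up_lo <- matrix(0, N, ncol(lo)); up_lo[seq(1, N, 2), ] <- lo
  up_hi <- matrix(0, N, ncol(hi)); up_hi[seq(1, N, 2), ] <- hi
  circ_conv_cols(up_lo, fb$h) + circ_conv_cols(up_hi, fb$g)
}

#' per-level lowpass/highpass filter pair of each tree ("a" or "b")
#'
#' Level 1: tree B is tree A delayed by one sample (both filters), which
#' keeps the shifted system an exact orthonormal basis. Levels >= 2: tree B
#' is the time-reversed quarter-delay filter, giving the half-sample offset
#' that makes the wavelet pair near-analytic.
#' @noRd
tree_filter <- function(tree, level) {
  h <- QSHIFT14
  if (level == 1L) {
    if (tree == "a") list(h = h, g = qmf_high(h))
    else list(h = c(0, h), g = c(0, qmf_high(h)))
  } else {
    hb <- if (tree == "a") h else rev(h)
    list(h = hb, g = qmf_high(hb))
  }
}

#' Forward 2-D dual-tree transform
#'
#' Keeps the four row/column tree combinations ("aa", "ab", "ba", "bb");
#' each is a complete orthonormal decimated wavelet decomposition.
#' @return list with `levels` (list per level of list per combo of
#'   LH/HL/HH), `low` (list per combo), `nlevels`.
#' @noRd
dtcwt_fwd <- function(x, nlevels) {
  combos <- c("aa", "ab", "ba", "bb")
  low <- list(aa = x, ab = x, ba = x, bb = x)
  out <- vector("list", nlevels)
  for (lev in seq_len(nlevels)) {
    bands <- list()
    for (cmb in combos) {
      hr <- tree_filter(substr(cmb, 1, 1), lev) # along columns (dim 1)
      hc <- tree_filter(substr(cmb, 2, 2), lev) # along rows (dim 2)
      s1 <- afb_cols(low[[cmb]], hr)
      t_lo <- afb_cols(t(s1$lo), hc)
      t_hi <- afb_cols(t(s1$hi), hc)
      bands[[cmb]] <- list(LH = t(t_lo$hi), HL = t(t_hi$lo), HH = t(t_hi$hi))
      low[[cmb]] <- t(t_lo$lo)
    }
    out[[lev]] <- bands
  }
  list(levels = out, low = low, nlevels = nlevels)
}

#' @noRd
dtcwt_inv <- function(dec) {
  combos <- c("aa", "ab", "ba", "bb")
  low <- dec$low
  for (lev in rev(seq_len(dec$nlevels))) {
    for (cmb in combos) {
      hr <- tree_filter(substr(cmb, 1, 1), lev)
      hc <- tree_filter(substr(cmb, 2, 2), lev)
      b <- dec$levels[[lev]][[cmb]]
      lo_cols <- t(sfb_cols(t(low[[cmb]]), t(b$LH), hc))
      hi_cols <- t(sfb_cols(t(b$HL), t(b$HH), hc))
      low[[cmb]] <- sfb_cols(lo_cols, hi_cols, hr)
    }
  }
  (low$aa + low$ab + low$ba + low$bb) / 4
}

#' threshold the six directional complex subbands formed from the four trees
#' @noRd
dtcwt_threshold <- function(dec, tau, mode) {
  shrink <- function(z) {
    m <- Mod(z)
    if (mode == "soft") z * pmax(1 - tau / pmax(m, 1e-300), 0)
    else z * (m >= tau)
  }
  for (lev in seq_len(dec$nlevels)) {
    for (s in c("LH", "HL", "HH")) {
      caa <- dec$levels[[lev]]$aa[[s]]; cbb <- dec$levels[[lev]]$bb[[s]]
      cab <- dec$levels[[lev]]$ab[[s]]; cba <- dec$levels[[lev]]$ba[[s]]
      z1 <- complex(real = caa - cbb, imaginary = cab + cba) / sqrt(2)
      z2 <- complex(real = caa + cbb, imaginary = cab - cba) / sqrt(2)
      z1 <- shrink(z1); z2 <- shrink(z2)
      dim(z1) <- dim(caa); dim(z2) <- dim(caa)
      dec$levels[[lev]]$aa[[s]] <- (Re(z1) + Re(z2)) / sqrt(2)
      dec$levels[[lev]]$bb[[s]] <- (Re(z2) - Re(z1)) / sqrt(2)
      dec$levels[[lev]]$ab[[s]] <- (Im(z1) + Im(z2)) / sqrt(2)
      dec$levels[[lev]]$ba[[s]] <- (Im(z1) - Im(z2)) / sqrt(2)
    }
  }
  dec
}
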