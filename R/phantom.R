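#' Specify a synthetic anatomical phantom
#'
#' Phantoms are Shepp-Logan-like compositions of constant-intensity ellipses
#' (a large "body" outline plus smaller internal structures, painted in
#' order) with optional small bright discs emulating nodular features.
#' Piecewise-constant structure with sharp edges is exactly what both the
#' total-variation and the patch-dictionary priors exploit, which makes
#' these phantoms a fair common testbed for all reconstruction routes.
#'
#' @param height,width image dimensions in pixels (at least 16).
#' @param n_ellipses number of constant-intensity ellipses (>= 1; the first
#'   is the large body outline).
#' @param nodule_count number of small bright discs.
#' @param nodule_radius_px disc radius in pixels.
#' @param intensity_range length-2 numeric in `[0, 1]`: intensities are drawn
#'   uniformly from this interval.
#' @param noise_sigma standard deviation of additive white Gaussian pixel
#'   noise applied after composition (0 for a clean phantom).
#' @param texture_amp amplitude (standard deviation) of a spatially
#'   correlated Gaussian random field added to the composition, emulating
#'   fine-grain tissue texture; real anatomies are not piecewise constant,
#'   and this field is what distinguishes priors that can represent local
#'   texture from those that flatten it. 0 disables.
#' @param texture_scale spectral width of the texture field (Gaussian
#'   envelope in normalized spatial frequency; larger = finer texture).
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, n_ellipses = 6,
                         nodule_count = 3, nodule_radius_px = 2,
                         intensity_range = c(0.2, 1), noise_sigma = 0,
                         texture_amp = 0, texture_scale = 0.3,
                         seed = 0) {
  if (height < 16 || width < 16)
    stop_invalid("phantom dimensions must be at least 16 x 16")
  if (n_ellipses < 1) stop_invalid("n_ellipses must be >= 1")
  if (nodule_count < 0 || nodule_radius_px <= 0)
    stop_invalid("invalid nodule configuration")
  if (length(intensity_range) != 2 || any(intensity_range < 0) ||
      any(intensity_range > 1) || diff(intensity_range) < 0)
    stop_invalid("intensity_range must be an increasing pair in [0, 1]")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  if (texture_amp < 0 || texture_scale <= 0)
    stop_invalid("invalid texture configuration")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_ellipses = as.integer(n_ellipses),
                 nodule_count = as.integer(nodule_count),
                 nodule_radius_px = nodule_radius_px,
                 intensity_range = intensity_range,
                 noise_sigma = noise_sigma, texture_amp = texture_amp,
                 texture_scale = texture_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image
#'
#' @param spec a [phantom_spec].
#' @return a `height x width` numeric matrix; values lie in `[0, 1]` before
#'   noise, and the result is bit-identical across calls with the same spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    # normalized coordinates in [-1, 1]
    yy <- matrix(seq(-1, 1, length.out = H), H, W)
    xx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    img <- matrix(0, H, W)
    lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
    for (k in seq_len(spec$n_ellipses)) {
      if (k == 1L) { # body outline: large centered ellipse
        cx <- 0; cy <- 0
        a <- runif(1, 0.75, 0.92); b <- runif(1, 0.75, 0.92)
        th <- 0
      } else {
        cx <- runif(1, -0.4, 0.4); cy <- runif(1, -0.4, 0.4)
        a <- runif(1, 0.12, 0.45); b <- runif(1, 0.12, 0.45)
        th <- runif(1, 0, pi)
      }
      val <- runif(1, lo, hi)
      xr <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
      yr <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      img[inside] <- val # painter's order keeps the image piecewise constant
    }
    if (spec$nodule_count > 0) {
      rpx <- spec$nodule_radius_px
      rx <- 2 * rpx / (W - 1); ry <- 2 * rpx / (H - 1)
      for (k in seq_len(spec$nodule_count)) {
        cx <- runif(1, -0.5, 0.5); cy <- runif(1, -0.5, 0.5)
        val <- runif(1, (lo + hi) / 2, hi) # nodules are bright
        inside <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
        img[inside] <- val
      }
    }
    if (spec$texture_amp > 0) {
      # band-limited Gaussian random field: white noise shaped by a
      # Gaussian spectral envelope, normalized to the requested amplitude
      w <- matrix(rnorm(H * W), H, W)
      dc <- dc_index(c(H, W))
      ry <- (seq_len(H) - dc[1]) / (H / 2)
      rx <- (seq_len(W) - dc[2]) / (W / 2)
      env <- exp(-outer(ry^2, rx^2, `+`) / (2 * spec$texture_scale^2))
      tex <- Re(ifft2c(fft2c(w) * env))
      img <- clip01(img + tex * (spec$texture_amp / stats::sd(tex)))
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    img
  })
}

#' Specify a k-space sampling mask
#'
#' @param pattern one of `"uniform_random"`, `"variable_density"`,
#'   `"radial_lines"`. Variable density retains low frequencies with
#'   probability decaying as a radial power law from the DC location, the
#'   standard compressed-sensing MRI practice.
#' @param sampling_rate fraction of k-space retained, in `(0, 1]`.
#' @param keep_dc if `TRUE` (default) the zero-frequency sample is always
#'   retained, anchoring the mean image intensity.
#' @param density_power exponent of the radial decay for
#'   `"variable_density"`.
#' @param n_lines number of radial spokes for `"radial_lines"` (chosen
#'   automatically from the rate if `NULL`).
#' @param seed integer seed.
#' @return an object of class `mask_spec`.
#' @export
mask_spec <- function(pattern = c("variable_density", "uniform_random",
                                  "radial_lines"),
                      sampling_rate = 0.4, keep_dc = TRUE,
                      density_power = 3, n_lines = NULL, seed = 0) {
  pattern <- match.arg(pattern)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0 || sampling_rate > 1)
    stop_invalid("sampling_rate must lie in (0, 1]")
  structure(list(pattern = pattern, sampling_rate = sampling_rate,
                 keep_dc = isTRUE(keep_dc), density_power = density_power,
                 n_lines = n_lines, seed = as.integer(seed)),
            class = "mask_spec")
}

#' Realize a boolean sampling mask
#'
#' The realized number of retained samples is within one sample of
#' `round(sampling_rate * n_pixels)` for all patterns (radial spokes are
#' trimmed/topped-up at random to hit the count), and the DC location is
#' forced on when `keep_dc` is set.
#'
#' Masks are made conjugate-symmetric (a sampled frequency implies its
#' mirror is sampled): the reconstruction targets here are real-valued
#' images, whose spectra are Hermitian, so symmetric sampling is the
#' self-consistent acquisition model -- and it makes the data-consistency
#' projection of a real image exact on the sampled entries.
#'
#' @param spec a [mask_spec].
#' @param shape integer vector `(rows, cols)`.
#' @return a logical matrix of the given shape.
#' @export
make_mask <- function(spec, shape) {
  stopifnot(inherits(spec, "mask_spec"))
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 2 || W < 2) stop_invalid("mask shape must be at least 2 x 2")
  n <- H * W
  k <- max(1L, as.integer(round(spec$sampling_rate * n)))
  dc <- dc_index(c(H, W))
  dci <- (dc[2] - 1L) * H + dc[1]
  with_seed(spec$seed, {
    mask <- matrix(FALSE, H, W)
    if (k >= n) {
      mask[] <- TRUE
    } else if (spec$pattern == "uniform_random") {
      mask[sample.int(n, k)] <- TRUE
    } else if (spec$pattern == "variable_density") {
      ry <- (seq_len(H) - dc[1]) / (H / 2)
      rx <- (seq_len(W) - dc[2]) / (W / 2)
      r <- sqrt(outer(ry^2, rx^2, `+`))
      w <- 1 / (1e-2 + r)^spec$density_power
      mask[sample.int(n, k, prob = as.vector(w))] <- TRUE
    } else { # radial_lines
      nl <- spec$n_lines
      if (is.null(nl)) nl <- max(1L, round(spec$sampling_rate * max(H, W) * pi / 2))
      ang <- seq(0, pi, length.out = nl + 1L)[-(nl + 1L)]
      rmax <- sqrt(H^2 + W^2) / 2
      tt <- seq(-rmax, rmax, by = 0.5)
      for (a in ang) {
        ii <- round(dc[1] + tt * sin(a)); jj <- round(dc[2] + tt * cos(a))
        ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
        mask[cbind(ii[ok], jj[ok])] <- TRUE
      }
      have <- sum(mask)
      if (have > k) { # trim random spoke pixels (never DC)
        on <- setdiff(which(mask), dci)
        mask[sample(on, have - k)] <- FALSE
      } else if (have < k) {
        off <- which(!mask)
        mask[sample(off, k - have)] <- TRUE
      }
    }
    if (spec$keep_dc && !mask[dc[1], dc[2]]) {
      # keep the count exact: drop one retained non-DC sample
      on <- setdiff(which(mask), dci)
      if (length(on) > 0 && sum(mask) >= k) mask[on[sample.int(length(on), 1)]] <- FALSE
      mask[dc[1], dc[2]] <- TRUE
    }
    conj_symmetrize(mask, k, dci)
  })
}

#' close a mask under frequency mirroring and trim back to the target count
#' @noRd
conj_symmetrize <- function(mask, k, dci) {
  H <- nrow(mask); W <- ncol(mask)
  dc <- dc_index(c(H, W))
  mi <- 2 * dc[1] - seq_len(H); mi[mi < 1 | mi > H] <- seq_len(H)[mi < 1 | mi > H]
  mj <- 2 * dc[2] - seq_len(W); mj[mj < 1 | mj > W] <- seq_len(W)[mj < 1 | mj > W]
  mirror <- function(m) m[mi, mj, drop = FALSE]
  mask <- mask | mirror(mask)
  excess <- sum(mask) - k
  if (excess >= 2) {
    idx <- matrix(seq_len(H * W), H, W)
    midx <- mirror(idx)
    # sampled mirror pairs (one representative each), never the DC sample
    cand <- which(mask & idx < midx & idx != dci & as.vector(midx) != dci)
    if (length(cand)) {
      drop <- cand[sample.int(length(cand), min(length(cand), excess %/% 2))]
      mask[drop] <- FALSE
      mask[midx[drop]] <- FALSE
    }
    excess <- sum(mask) - k
  }
  if (excess == 1) {
    # a self-symmetric sample (Nyquist row/column) can be dropped alone
    idx <- matrix(seq_len(H * W), H, W)
    selfsym <- which(mask & idx == mirror(idx) & idx != dci)
    if (length(selfsym)) mask[selfsym[sample.int(length(selfsym), 1)]] <- FALSE
  }
  mask
}

#' Construct an undersampled k-space record
#'
#' @param data complex matrix of k-space values (zero where unsampled).
#' @param mask logical matrix of sampled locations.
#' @param sampling_rate retained fraction (recomputed from the mask if
#'   missing).
#' @return an object of class `kspace_sample`.
#' @export
kspace_sample <- function(data, mask, sampling_rate = mean(mask)) {
  if (!is.matrix(data) || !is.matrix(mask) || !all(dim(data) == dim(mask)))
    stop_dim("k-space data and mask must be matrices of equal shape")
  data[!mask] <- 0 + 0i
  structure(list(data = data, mask = mask, sampling_rate = sampling_rate),
            class = "kspace_sample")
}

#' Simulate an accelerated MR acquisition
#'
#' Forward model `y = mask o (F x + n)` with `F` the centered unitary
#' Fourier transform and `n` circular complex Gaussian noise of standard
#' deviation `noise_sigma` per real/imaginary component -- the standard MR
#' noise model. Unsampled entries are stored as zero.
#'
#' @param image real image matrix.
#' @param mask logical sampling mask of the same shape.
#' @param noise_sigma per-component noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return a [kspace_sample].
#' @export
simulate_acquisition <- function(image, mask, noise_sigma = 0, seed = 0) {
  assert_image(image)
  if (!all(dim(image) == dim(mask))) stop_dim("image/mask shape mismatch")
  kf <- fft2c(image)
  if (noise_sigma > 0) {
    kf <- kf + with_seed(seed, {
      n <- length(kf)
      matrix(complex(real = rnorm(n, 0, noise_sigma),
                     imaginary = rnorm(n, 0, noise_sigma)), nrow(kf), ncol(kf))
    })
  }
  kf[!mask] <- 0 + 0i
  kspace_sample(kf, mask, mean(mask))
}
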