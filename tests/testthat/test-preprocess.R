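test_that("dual-tree transform reconstructs exactly without thresholding", {
  set.seed(1)
  for (d in list(c(64, 64), c(50, 45), c(32, 48))) {
    x <- matrix(runif(d[1] * d[2]), d[1], d[2])
    out <- dtcwt_denoise(x, wavelet_spec(levels = 2, threshold = 0))
    expect_lt(max(abs(out - x)), 1e-6)
  }
  z <- matrix(0, 64, 64)
  expect_equal(dtcwt_denoise(z, wavelet_spec(3, 0.1)), z)
  expect_error(dtcwt_denoise(matrix(0, 16, 16), wavelet_spec(3, 0)),
               class = "dictmri_invalid_spec")
})

test_that("magnitude thresholding denoises a noisy phantom", {
  ph <- fixture_phantom(seed = 3, texture = 0)
  set.seed(7)
  sigma <- 0.05
  noisy <- ph + matrix(rnorm(length(ph), 0, sigma), nrow(ph))
  den <- dtcwt_denoise(noisy, wavelet_spec(3, 3 * sigma, "soft"))
  expect_gt(psnr(ph, den), psnr(ph, noisy))
})

test_that("white top-hat matches hand-computed cases", {
  se <- struct_element("square", 3)
  flat <- matrix(0.6, 9, 9)
  expect_equal(white_top_hat(flat, se), matrix(0, 9, 9))
  # isolated bright pixel survives the top-hat unchanged
  spike <- matrix(0, 7, 7); spike[4, 4] <- 1
  expect_equal(white_top_hat(spike, se), spike)
  # single-pixel footprint: opening is the identity
  one <- struct_element("square", 1)
  set.seed(2)
  rnd <- matrix(runif(64), 8, 8)
  expect_equal(white_top_hat(rnd, one), matrix(0, 8, 8))
})

test_that("black top-hat is the complement dual of the white top-hat", {
  se <- struct_element("square", 3)
  flat <- matrix(0.4, 9, 9)
  expect_equal(black_top_hat(flat, se), matrix(0, 9, 9))
  set.seed(4)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_equal(black_top_hat(x, se), white_top_hat(1 - x, se),
               tolerance = 1e-12)
  # single dark pit: output equals the pit depth at that pixel
  pit <- matrix(0.8, 9, 9); pit[5, 5] <- 0.3
  bth <- black_top_hat(pit, se)
  expect_equal(bth[5, 5], 0.5, tolerance = 1e-12)
  expect_true(all(bth >= 0))
})

test_that("opening <= original <= closing pixelwise", {
  se <- struct_element("disc", 5)
  for (seed in c(1, 9)) {
    x <- fixture_phantom(seed = seed)
    expect_true(all(gray_opening(x, se) <= x + 1e-12))
    expect_true(all(gray_closing(x, se) >= x - 1e-12))
    expect_true(all(white_top_hat(x, se) >= 0))
    expect_true(all(black_top_hat(x, se) >= 0))
  }
})

test_that("spatial enhancement applies monotone point maps", {
  x <- fixture_phantom(seed = 5)
  expect_equal(enhance_spatial(x, "gamma", gamma = 1), x)
  expect_equal(enhance_spatial(matrix(0.25, 4, 4), "gamma",
                               gamma = 0.5)[1, 1], 0.5)
  y <- matrix(seq(0.2, 0.7, length.out = 25), 5, 5)
  st <- enhance_spatial(y, "stretch")
  expect_equal(range(st), c(0, 1))
  he <- enhance_spatial(x, "histeq")
  expect_true(all(he >= 0 & he <= 1))
  # order preservation of the equalization map
  o <- order(as.vector(x))
  expect_true(all(diff(as.vector(he)[o]) >= 0))
  expect_error(enhance_spatial(x, "gamma", gamma = -1),
               class = "dictmri_invalid_spec")
})

test_that("frequency enhancement obeys closed-form gain profiles", {
  x <- fixture_phantom(seed = 6)
  flat <- enhance_frequency(x, list(profile = "flat", gain = 1))
  expect_lt(max(abs(flat - x)), 1e-10)
  # zero gain everywhere except DC collapses the image to its mean
  dconly <- enhance_frequency(x, list(profile = "dc_only"))
  expect_lt(max(abs(dconly - mean(x))), 1e-10)
  expect_error(enhance_frequency(x, list(profile = "butterworth_highpass",
                                         offset = -0.5)),
               class = "dictmri_invalid_spec")
})

test_that("high-boost enhancement raises local contrast at edges", {
  ph <- fixture_phantom(seed = 8, texture = 0)
  hb <- enhance_frequency(ph, list(profile = "gaussian_high_boost",
                                   boost = 1, sigma = 0.25))
  base <- local_range3(ph)
  # edge pixels: top decile of local intensity range
  edges <- base >= stats::quantile(base[base > 0], 0.9)
  frac <- mean(local_range3(hb)[edges] >= base[edges] - 1e-9)
  expect_gte(frac, 0.9)
})
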