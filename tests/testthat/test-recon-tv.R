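test_that("anisotropic TV matches hand computations and homogeneity", {
  expect_equal(tv_anisotropic(matrix(0.7, 10, 10)), 0)
  # two horizontal unit steps, no vertical steps
  expect_equal(tv_anisotropic(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  set.seed(1)
  x <- matrix(runif(64), 8, 8)
  for (cc in c(-2.5, 0.3)) {
    expect_equal(tv_anisotropic(cc * x), abs(cc) * tv_anisotropic(x),
                 tolerance = 1e-12)
  }
})

test_that("smoothed TV obeys its closed form and bounds", {
  n <- 12 * 9
  expect_equal(tv_smoothed(matrix(0.3, 12, 9), phi = 0.01), n * 0.01,
               tolerance = 1e-12)
  set.seed(2)
  x <- matrix(runif(100), 10, 10)
  # phi -> 0 approaches isotropic TV within n * phi
  d <- dictmri:::fwd_diff(x)
  tv_iso <- sum(sqrt(d$dx^2 + d$dy^2))
  for (phi in c(1e-2, 1e-3)) {
    v <- tv_smoothed(x, phi)
    expect_gte(v, tv_iso)
    expect_lt(v - tv_iso, phi * length(x))
  }
  expect_gt(tv_smoothed(x, 0.1), tv_smoothed(x, 0.01))
  expect_error(tv_smoothed(x, 0), class = "dictmri_invalid_spec")
})

test_that("smoothed-TV gradient matches central finite differences", {
  set.seed(3)
  x <- matrix(runif(15 * 13), 15, 13)
  phi <- 1e-2
  g <- dictmri:::tv_smoothed_grad(x, phi)
  eps <- 1e-6
  idx <- cbind(sample(15, 10, replace = TRUE), sample(13, 10, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    xp <- x; xp[idx[r, 1], idx[r, 2]] <- xp[idx[r, 1], idx[r, 2]] + eps
    xm <- x; xm[idx[r, 1], idx[r, 2]] <- xm[idx[r, 1], idx[r, 2]] - eps
    fd <- (tv_smoothed(xp, phi) - tv_smoothed(xm, phi)) / (2 * eps)
    expect_lt(abs(fd - g[idx[r, 1], idx[r, 2]]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("full sampling without regularization returns the exact image", {
  ph <- fixture_phantom(seed = 4)
  s <- simulate_acquisition(ph, matrix(TRUE, 64, 64), noise_sigma = 0)
  r <- reconstruct_tv(s, tv_solve_spec(lambda_tv = 0, max_iters = 10))
  expect_lt(max(abs(r$image - ph)), 1e-6)
})

test_that("unregularized objective is minimized by the zero-filled start", {
  ph <- fixture_phantom(seed = 5)
  s <- fixture_sample(ph, rate = 0.4, seed = 9)
  r <- reconstruct_tv(s, tv_solve_spec(lambda_tv = 0, max_iters = 30))
  # the optimum attains (numerically) zero data misfit
  expect_lt(utils::tail(r$log$objective, 1), 1e-8)
})

test_that("the TV solve descends monotonically and beats zero-filled", {
  ph <- fixture_phantom(seed = 0)
  s <- fixture_sample(ph, rate = 0.5, seed = 0)
  zf_psnr <- psnr(ph, zero_filled(s))
  best <- -Inf
  for (lam in 10^seq(-4, -1)) {
    r <- reconstruct_tv(s, tv_solve_spec(lambda_tv = lam, max_iters = 100))
    expect_true(all(diff(r$log$objective) <= 1e-9))
    best <- max(best, psnr(ph, r$image))
  }
  expect_gt(best, zf_psnr + 1)
})

test_that("reconstruction quality is non-decreasing in sampling rate", {
  ph <- fixture_phantom(seed = 1)
  p <- vapply(c(0.3, 0.6), function(rate) {
    s <- fixture_sample(ph, rate = rate, seed = 2)
    psnr(ph, reconstruct_tv(s, tv_solve_spec(lambda_tv = 1e-3,
                                             max_iters = 80))$image)
  }, 0)
  expect_gt(p[2], p[1])
})
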