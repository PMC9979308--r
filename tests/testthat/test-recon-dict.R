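test_that("patch extraction counts and reassembly identity hold", {
  set.seed(1)
  img8 <- matrix(runif(64), 8, 8)
  e <- extract_patches(img8, patch_config(8, 8, remove_mean = FALSE))
  expect_identical(ncol(e$Y), 1L)
  expect_equal(e$Y[, 1], as.vector(img8))

  img16 <- matrix(runif(256), 16, 16)
  e2 <- extract_patches(img16, patch_config(8, 4, remove_mean = FALSE))
  expect_identical(ncol(e2$Y), 9L) # 3 x 3 grid of origins
  expect_equal(reassemble_patches(e2), img16, tolerance = 1e-12)

  # mean removal restores exactly too
  e3 <- extract_patches(img16, patch_config(8, 3, remove_mean = TRUE))
  expect_equal(reassemble_patches(e3), img16, tolerance = 1e-12)
  expect_error(extract_patches(img8, patch_config(16, 4)),
               class = "dictmri_invalid_spec")
})

test_that("omp recovers exact representations in easy regimes", {
  D <- diag(8)
  x <- omp_code(3 * D[, 5], D, T = 1)
  expect_equal(x[5], 3)
  expect_identical(sum(x != 0), 1L)

  # orthonormal atoms, two-term combination, exact recovery at T = 2
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  y <- 2 * Q[, 1] + 1 * Q[, 2]
  x2 <- omp_code(y, Q, T = 2)
  expect_equal(x2[1:2], c(2, 1), tolerance = 1e-10)
  expect_lt(sqrt(sum((y - Q %*% x2)^2)), 1e-10)

  # T = 0: zero code, residual is the full norm
  x0 <- omp_code(y, Q, T = 0)
  expect_true(all(x0 == 0))
  expect_warning(omp_code(y, Q, T = 10), "clipped")
})

test_that("omp is never better than, and often equal to, the l0 oracle", {
  set.seed(0)
  n_equal <- 0
  for (trial in 1:100) {
    p <- sample(4:6, 1); K <- sample(6:8, 1); T <- sample(1:2, 1)
    D <- matrix(rnorm(p * K), p)
    D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
    y <- rnorm(p)
    xg <- omp_code(y, D, T)
    expect_lte(sum(xg != 0), T)
    rg <- sqrt(sum((y - D %*% xg)^2))
    opt <- sparse_oracle(D, y, T)
    # greedy can never beat the exhaustive optimum
    expect_gte(rg, opt$residual - 1e-9)
    if (rg <= opt$residual + 1e-9) n_equal <- n_equal + 1
  }
  # the greedy path is optimal most of the time on these instances
  expect_gt(n_equal, 50)
})

test_that("dictionary learning descends and respects the sparsity cap", {
  ph <- fixture_phantom(seed = 3)
  Y <- extract_patches(ph, patch_config(8, 4))$Y
  fit0 <- learn_dictionary(Y, n_atoms = 64, T = 8, iters = 0, seed = 0)
  expect_length(fit0$objective, 1)
  expect_equal(fit0$objective[1], sum((Y - fit0$atoms %*% fit0$codes)^2),
               tolerance = 1e-8)

  fit <- learn_dictionary(Y, n_atoms = 64, T = 8, iters = 10, seed = 0)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_lte(utils::tail(fit$objective, 1), fit$objective[1])
  expect_true(all(colSums(fit$codes != 0) <= 8))
  expect_equal(colSums(fit$atoms^2), rep(1, 64), tolerance = 1e-8)
  expect_error(learn_dictionary(matrix(0, 4, 10), 4),
               class = "dictmri_invalid_spec")
})

test_that("reconstruction enforces exact data consistency", {
  ph <- fixture_phantom(seed = 5)
  # full sampling: consistency forces the ground truth back
  s_full <- simulate_acquisition(ph, matrix(TRUE, 64, 64), noise_sigma = 0)
  r_full <- reconstruct_dict(s_full, patch_config(8, 4),
                             dict_recon_spec(n_atoms = 64, T = 4,
                                             learn_iters = 2,
                                             outer_iters = 1))
  expect_lt(max(abs(r_full$image - ph)), 1e-6)

  s <- fixture_sample(ph, rate = 0.4, seed = 6)
  r <- reconstruct_dict(s, patch_config(8, 3),
                        dict_recon_spec(n_atoms = 96, T = 4, learn_iters = 4,
                                        outer_iters = 3))
  k <- fft2c(r$image)
  expect_lt(max(Mod(k[s$mask] - s$data[s$mask])), 1e-10)
  expect_gt(psnr(ph, pmin(pmax(r$image, 0), 1)), psnr(ph, zero_filled(s)))
})
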