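test_that("phantoms are deterministic, bounded, piecewise constant", {
  sp <- phantom_spec(64, 64, n_ellipses = 1, nodule_count = 0, seed = 1)
  ph <- make_phantom(sp)
  expect_length(unique(as.vector(ph)), 2) # one ellipse on background
  expect_true(all(ph >= 0 & ph <= 1))
  expect_identical(ph, make_phantom(sp)) # pure function of the spec
  expect_error(phantom_spec(8, 8), class = "dictmri_invalid_spec")
})

test_that("phantom value histogram matches the frozen regression fixture", {
  ph <- make_phantom(phantom_spec(64, 64, n_ellipses = 3, nodule_count = 2,
                                  seed = 7))
  v <- sort(unique(as.vector(ph)))
  expect_equal(v, c(0, 0.292558223009109, 0.332684387639165,
                    0.562758216075599, 0.603481839969754, 0.855779576767236),
               tolerance = 1e-12)
  expect_equal(as.integer(table(factor(as.vector(ph), levels = v))),
               c(1752L, 1894L, 190L, 235L, 12L, 13L))
})

test_that("masks hit the exact retained count and honor keep_dc", {
  m <- make_mask(mask_spec("uniform_random", 1.0), c(16, 16))
  expect_true(all(m))
  m <- make_mask(mask_spec("uniform_random", 0.5, seed = 2), c(32, 32))
  expect_identical(sum(m), 512L)
  dc <- dc_index(c(32, 32))
  for (pat in c("uniform_random", "variable_density", "radial_lines")) {
    for (seed in 1:100) {
      mk <- make_mask(mask_spec(pat, 0.2, keep_dc = TRUE, seed = seed),
                      c(24, 24))
      expect_true(mk[dc_index(c(24, 24))[1], dc_index(c(24, 24))[2]])
      expect_lte(abs(sum(mk) - round(0.2 * 24 * 24)), 1)
    }
  }
  expect_error(mask_spec("uniform_random", 0), class = "dictmri_invalid_spec")
  expect_error(mask_spec("uniform_random", 1.2), class = "dictmri_invalid_spec")
})

test_that("acquisition is a unitary round trip at full sampling", {
  ph <- fixture_phantom(seed = 4)
  m <- matrix(TRUE, 64, 64)
  s <- simulate_acquisition(ph, m, noise_sigma = 0)
  expect_lt(max(abs(Re(ifft2c(s$data)) - ph)), 1e-10)
  # sampled entries equal F(x) exactly on any mask, unsampled are zero
  m2 <- make_mask(mask_spec("variable_density", 0.3, seed = 5), dim(ph))
  s2 <- simulate_acquisition(ph, m2, noise_sigma = 0)
  k <- fft2c(ph)
  expect_lt(max(Mod(s2$data[m2] - k[m2])), 1e-12)
  expect_true(all(s2$data[!m2] == 0))
  expect_error(simulate_acquisition(ph, matrix(TRUE, 8, 8)),
               class = "dictmri_dimension_error")
})

test_that("k-space noise has the prescribed complex variance", {
  ph <- fixture_phantom(seed = 6)
  m <- matrix(TRUE, 64, 64)
  s <- simulate_acquisition(ph, m, noise_sigma = 0.01, seed = 42)
  resid <- s$data - fft2c(ph)
  v <- mean(Mod(resid)^2) # complex variance = 2 sigma^2 (real + imag)
  expect_lt(abs(v - 2 * 0.01^2) / (2 * 0.01^2), 0.1)
})

test_that("cohort draws respect prior and misclassification structure", {
  labels <- c("T1-2", "T3", "T4")
  ident <- diag(3)
  tb <- simulate_cohort(cohort_spec(146, labels, c(41, 58, 47) / 146,
                                    ident, seed = 1))
  expect_true(all(tb$counts[upper.tri(tb$counts)] == 0))
  expect_true(all(tb$counts[lower.tri(tb$counts)] == 0))
  expect_equal(coincidence_rate(tb), 1)
  expect_identical(sum(tb$counts), 146L)

  # law of large numbers: column margins converge to the prior
  big <- simulate_cohort(cohort_spec(100000, labels, c(41, 58, 47) / 146,
                                     ident, seed = 2))
  expect_lt(max(abs(colSums(big$counts) / 100000 - c(41, 58, 47) / 146)),
            0.01)

  # fully uniform misclassification: per-stage sensitivity ~ 1/3
  unif <- matrix(1 / 3, 3, 3)
  tb3 <- simulate_cohort(cohort_spec(50000, labels, rep(1 / 3, 3), unif,
                                     seed = 3))
  sens <- vapply(1:3, function(k) sensitivity(tb3, k), 0)
  expect_lt(max(abs(sens - 1 / 3)), 0.03)

  expect_error(cohort_spec(10, labels, c(0.5, 0.5, 0.5), ident),
               class = "dictmri_invalid_spec")
  bad <- ident; bad[1, 1] <- 0.5
  expect_error(cohort_spec(10, labels, rep(1 / 3, 3), bad),
               class = "dictmri_invalid_spec")
})
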