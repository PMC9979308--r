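# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (loops, enumeration) and share no code
# with the implementation paths they check.

# straight-from-definition SSIM: explicit sliding window, Gaussian weights
# recomputed per window, no convolution shortcuts
ssim_naive <- function(a, b, data_range = 1, win = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  r <- seq_len(win) - (win + 1) / 2
  w <- outer(exp(-r^2 / (2 * sigma^2)), exp(-r^2 / (2 * sigma^2)))
  w <- w / sum(w)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in seq_len(H - win + 1)) {
    for (j in seq_len(W - win + 1)) {
      pa <- a[i:(i + win - 1), j:(j + win - 1)]
      pb <- b[i:(i + win - 1), j:(j + win - 1)]
      mua <- sum(w * pa); mub <- sum(w * pb)
      va <- sum(w * pa^2) - mua^2
      vb <- sum(w * pb^2) - mub^2
      cab <- sum(w * pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# exhaustive best-support T-sparse projection by enumeration of all
# supports of size <= T (the l0 oracle)
sparse_oracle <- function(D, y, T) {
  K <- ncol(D)
  best_res <- sqrt(sum(y^2))
  best_x <- numeric(K)
  for (t in seq_len(T)) {
    for (S in utils::combn(K, t, simplify = FALSE)) {
      Ds <- D[, S, drop = FALSE]
      coef <- tryCatch(qr.solve(Ds, y), error = function(e) NULL)
      if (is.null(coef)) next
      res <- sqrt(sum((y - Ds %*% coef)^2))
      if (res < best_res - 1e-14) {
        best_res <- res
        best_x <- numeric(K); best_x[S] <- coef
      }
    }
  }
  list(x = best_x, residual = best_res)
}

# 3x3 local intensity range (max - min), computed by explicit shifts
local_range3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  hi <- x; lo <- x
  for (di in -1:1) for (dj in -1:1) {
    ii <- pmin(pmax(seq_len(H) + di, 1), H)
    jj <- pmin(pmax(seq_len(W) + dj, 1), W)
    s <- x[ii, jj]
    hi <- pmax(hi, s); lo <- pmin(lo, s)
  }
  hi - lo
}

# a small fixed textured phantom + acquisition for reuse across files
fixture_phantom <- function(seed = 3, texture = 0.03) {
  make_phantom(phantom_spec(64, 64, texture_amp = texture, seed = seed))
}

fixture_sample <- function(image, rate = 0.4, seed = 11, noise = 0) {
  m <- make_mask(mask_spec("variable_density", rate, seed = seed), dim(image))
  simulate_acquisition(image, m, noise_sigma = noise, seed = seed + 1)
}
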