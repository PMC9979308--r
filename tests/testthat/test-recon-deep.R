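test_that("forward pass honors degenerate architectures exactly", {
  set.seed(1)
  x <- matrix(runif(64), 8, 8)
  zero_net <- conv_net(list(c(3, 1, 4), c(3, 4, 1)), seed = 0)
  for (l in seq_along(zero_net$layers)) {
    zero_net$layers[[l]]$w[] <- 0
    zero_net$layers[[l]]$b[] <- 0
  }
  expect_equal(deep_forward(zero_net, x), matrix(0, 8, 8))

  id_net <- conv_net(list(c(1, 1, 1)), seed = 0)
  id_net$layers[[1]]$w[] <- 1
  id_net$layers[[1]]$b[] <- 0
  expect_equal(deep_forward(id_net, x), x, tolerance = 1e-12)

  rnd <- conv_net(list(c(5, 1, 6), c(3, 6, 1)), seed = 3)
  expect_identical(deep_forward(rnd, x), deep_forward(rnd, x))
  expect_error(conv_net(list(c(3, 1, 4), c(3, 8, 1))),
               class = "dictmri_invalid_spec")
})

test_that("cost decomposes exactly into data and decay terms", {
  set.seed(2)
  x <- matrix(runif(36), 6, 6)
  id_net <- conv_net(list(c(1, 1, 1)), weight_decay = 0, seed = 0)
  id_net$layers[[1]]$w[] <- 1; id_net$layers[[1]]$b[] <- 0
  expect_equal(deep_cost(id_net, list(x), list(x))$total, 0)

  # constant offset of 0.1 over m pixels: data term = 0.5 * m * 0.01
  y <- x - 0.1
  cst <- deep_cost(id_net, list(x), list(y))
  expect_equal(cst$data, 0.5 * 36 * 0.01, tolerance = 1e-10)

  zd <- conv_net(list(c(3, 1, 2), c(3, 2, 1)), weight_decay = 0.5, seed = 1)
  for (l in seq_along(zd$layers)) zd$layers[[l]]$w[] <- 0
  cst2 <- deep_cost(zd, list(x), list(y))
  expect_equal(cst2$decay, 0)
  expect_equal(cst2$total, cst2$data + cst2$decay, tolerance = 1e-9)
  expect_error(deep_cost(zd, list(), list()), class = "dictmri_invalid_spec")
})

test_that("parameter gradients match central finite differences", {
  set.seed(3)
  net <- conv_net(list(c(3, 1, 4), c(3, 4, 1)), weight_decay = 0, seed = 1)
  xs <- list(matrix(runif(64), 8, 8))
  ys <- list(matrix(runif(64), 8, 8))
  g <- dictmri:::.deep_batch_grad_cpp(xs, ys, net$layers)
  eps <- 1e-5
  worst <- 0
  for (t in 1:20) {
    l <- sample(2, 1)
    i <- sample(length(net$layers[[l]]$w), 1)
    np <- net; np$layers[[l]]$w[i] <- np$layers[[l]]$w[i] + eps
    nm <- net; nm$layers[[l]]$w[i] <- nm$layers[[l]]$w[i] - eps
    fd <- (deep_cost(np, xs, ys)$data - deep_cost(nm, xs, ys)$data) / (2 * eps)
    worst <- max(worst, abs(fd - g$grad_w[[l]][i]) / max(abs(fd), 1e-8))
  }
  expect_lt(worst, 1e-4)
})

test_that("the descent update follows its scalar closed form", {
  # single 1x1 conv on a 1x1 image: cost = 0.5 (w c + b - t)^2
  net <- conv_net(list(c(1, 1, 1)), learning_rate = 0.2, weight_decay = 0,
                  seed = 0)
  net$layers[[1]]$w[] <- 0.8; net$layers[[1]]$b[] <- 0.1
  cval <- 0.5; tval <- 0.9
  xs <- list(matrix(cval, 1, 1)); ys <- list(matrix(tval, 1, 1))
  stepped <- sgd_step(net, xs, ys)
  resid <- 0.8 * cval + 0.1 - tval
  expect_equal(stepped$layers[[1]]$w[1], 0.8 - 0.2 * resid * cval,
               tolerance = 1e-12)
  expect_equal(stepped$layers[[1]]$b[1], 0.1 - 0.2 * resid,
               tolerance = 1e-12)
  # alpha = 0 leaves everything untouched
  frozen <- sgd_step(net, xs, ys, alpha = 0)
  expect_identical(frozen$layers, net$layers)
})

test_that("the net can overfit a single pair", {
  ph <- make_phantom(phantom_spec(32, 32, texture_amp = 0.03, seed = 5))
  s <- fixture_sample(ph, rate = 0.4, seed = 6)
  pair <- list(list(x = zero_filled(s), y = ph))
  net0 <- conv_net(list(c(9, 1, 16), c(1, 16, 8), c(5, 8, 1)),
                   learning_rate = 5e-3, weight_decay = 0, seed = 0)
  cost0 <- deep_cost(net0, list(pair[[1]]$x), list(pair[[1]]$y))$data
  fit <- train_deep(pair, split = c(1, 0), epochs = 500, net = net0,
                    optimizer = "adam")
  expect_lt(utils::tail(fit$log$data, 1), 0.01 * cost0)
})

test_that("weight decay shrinks the learned weights", {
  ph <- make_phantom(phantom_spec(32, 32, texture_amp = 0.03, seed = 7))
  s <- fixture_sample(ph, rate = 0.4, seed = 8)
  pair <- list(list(x = zero_filled(s), y = ph))
  wnorm <- function(lambda) {
    net0 <- conv_net(list(c(5, 1, 6), c(3, 6, 1)), learning_rate = 2e-4,
                     weight_decay = lambda, seed = 0)
    fit <- train_deep(pair, split = c(1, 0), epochs = 40, net = net0)
    sum(vapply(fit$net$layers, function(l) sum(l$w^2), 0))
  }
  expect_lt(wnorm(1e3), wnorm(0))
})

test_that("training is deterministic under a fixed seed", {
  ph <- make_phantom(phantom_spec(32, 32, texture_amp = 0.03, seed = 9))
  s <- fixture_sample(ph, rate = 0.4, seed = 10)
  pairs <- list(list(x = zero_filled(s), y = ph),
                list(x = zero_filled(s) * 0.9, y = ph))
  run <- function() {
    net0 <- conv_net(list(c(5, 1, 4), c(3, 4, 1)), learning_rate = 2e-4,
                     seed = 2)
    train_deep(pairs, split = c(2, 0), epochs = 10, net = net0,
               shuffle_seed = 4)$log
  }
  expect_identical(run(), run())
})

test_that("identity net plus data consistency returns the truth at rate 1", {
  ph <- fixture_phantom(seed = 11)
  s <- simulate_acquisition(ph, matrix(TRUE, 64, 64), noise_sigma = 0)
  id_net <- conv_net(list(c(1, 1, 1)), seed = 0)
  id_net$layers[[1]]$w[] <- 1; id_net$layers[[1]]$b[] <- 0
  out <- reconstruct_deep(s, id_net, data_consistency = TRUE)
  expect_lt(max(abs(out - ph)), 1e-6)
})
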