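#' Create the convolutional reconstruction network
#'
#' A small image-restoration stack mapping a degraded (zero-filled)
#' reconstruction to a clean image: same-padding convolutions with ReLU
#' between layers and a final linear convolution, spatial shape preserved
#' throughout. The default is the smallest standard restoration
#' architecture: 9x9 -> 64 channels, 1x1 -> 32, 5x5 -> 1.
#'
#' @param layers list of layer shapes, each `c(kernel, in_channels,
#'   out_channels)` with odd kernels; the first layer must take 1 channel
#'   and the last must produce 1.
#' @param learning_rate gradient-descent learning rate (the alpha of the
#'   update rule `W <- W - alpha * dH/dW`).
#' @param weight_decay weight-decay coefficient lambda of the cost
#'   `H = (1/n) sum_i 0.5 ||h(x_i) - y_i||^2 + (lambda/2) sum W^2`
#'   (biases excluded from the decay term).
#' @param seed initialization seed (He-scaled Gaussian weights, zero
#'   biases).
#' @return an object of class `conv_net` with elements `layers` (each with
#'   4-D weight array `w` and bias vector `b`), `learning_rate`,
#'   `weight_decay`, `seed`, `n_params`.
#' @export
conv_net <- function(layers = list(c(9, 1, 64), c(1, 64, 32), c(5, 32, 1)),
                     learning_rate = 0.1, weight_decay = 0, seed = 0) {
  if (learning_rate < 0) stop_invalid("learning_rate must be >= 0")
  if (weight_decay < 0) stop_invalid("weight_decay must be >= 0")
  if (layers[[1]][2] != 1 || layers[[length(layers)]][3] != 1)
    stop_invalid("network must map 1 channel to 1 channel")
  for (i in seq_along(layers)[-1])
    if (layers[[i]][2] != layers[[i - 1]][3])
      stop_invalid("channel mismatch between layers ", i - 1, " and ", i)
  lay <- with_seed(seed, lapply(layers, function(sh) {
    k <- sh[1]; cin <- sh[2]; cout <- sh[3]
    if (k %% 2 == 0) stop_invalid("kernel sides must be odd")
    fan_in <- k * k * cin
    w <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
               dim = c(k, k, cin, cout))
    list(w = w, b = numeric(cout))
  }))
  structure(list(layers = lay, learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 n_params = sum(vapply(lay, function(l)
                   length(l$w) + length(l$b), 0))),
            class = "conv_net")
}

#' Network forward pass
#'
#' @param net a [conv_net].
#' @param image real matrix, normalized to `[0, 1]`.
#' @return the network output, same shape; deterministic.
#' @export
deep_forward <- function(net, image) {
  stopifnot(inherits(net, "conv_net"))
  assert_image(image)
  .deep_forward_cpp(image, net$layers)
}

#' Training cost with exact decomposition
#'
#' `total = data + decay` with
#' `data = (1/n) sum_i 0.5 * ||h(x_i) - y_i||^2` (squared error summed over
#' pixels, averaged over the batch) and `decay = (lambda/2) * sum(W^2)`
#' over all convolution weights, biases excluded.
#'
#' @param net a [conv_net].
#' @param xs,ys lists of degraded inputs and clean targets (equal length,
#'   `n >= 1`).
#' @return list with `total`, `data`, `decay`.
#' @export
deep_cost <- function(net, xs, ys) {
  stopifnot(inherits(net, "conv_net"))
  if (!length(xs) || length(xs) != length(ys)) stop_invalid("empty or mismatched batch")
  data <- mean(vapply(seq_along(xs), function(i) {
    0.5 * sum((deep_forward(net, xs[[i]]) - ys[[i]])^2)
  }, 0))
  decay <- 0.5 * net$weight_decay *
    sum(vapply(net$layers, function(l) sum(l$w^2), 0))
  list(total = data + decay, data = data, decay = decay)
}

#' One gradient-descent step
#'
#' Updates every weight and bias by `-alpha` times its gradient of the full
#' cost (data term plus weight decay; biases carry no decay). `alpha = 0`
#' leaves the network unchanged.
#'
#' @inheritParams deep_cost
#' @param alpha learning rate (defaults to the network's).
#' @param lambda weight decay (defaults to the network's).
#' @return the updated [conv_net].
#' @export
sgd_step <- function(net, xs, ys, alpha = net$learning_rate,
                     lambda = net$weight_decay) {
  stopifnot(inherits(net, "conv_net"))
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  g <- .deep_batch_grad_cpp(xs, ys, net$layers)
  for (l in seq_along(net$layers)) {
    gw <- g$grad_w[[l]] + lambda * net$layers[[l]]$w
    gb <- g$grad_b[[l]]
    if (any(!is.finite(gw)) || any(!is.finite(gb)))
      stop("non-finite gradient encountered in layer ", l)
    net$layers[[l]]$w <- net$layers[[l]]$w - alpha * gw
    net$layers[[l]]$b <- net$layers[[l]]$b - alpha * gb
  }
  net
}

#' Train the deep-dictionary reconstructor
#'
#' Mini-batch stochastic gradient descent on pairs of (degraded, clean)
#' images. The degraded inputs are zero-filled reconstructions; the clean
#' targets are the ground-truth images. Logs the exact cost decomposition
#' and train/test PSNR per epoch and returns the parameters of the epoch
#' with the best test PSNR (falling back to train PSNR when no test pairs
#' are supplied).
#'
#' @param pairs list of `list(x = degraded, y = clean)` image pairs.
#' @param split integer vector `c(n_train, n_test)`; the first `n_train`
#'   pairs train, the following `n_test` pairs are held out (disjoint by
#'   construction).
#' @param epochs training epochs.
#' @param net a [conv_net] (its `learning_rate`/`weight_decay` drive the
#'   updates).
#' @param batch_size mini-batch size.
#' @param shuffle_seed seed for the per-epoch mini-batch shuffle.
#' @param optimizer `"sgd"` (default): the plain gradient-descent update
#'   `W <- W - alpha * dH/dW`, exactly as in [sgd_step()]. `"adam"`:
#'   adaptive-moment estimation on the same gradients -- an optional
#'   accelerator for benchmark-scale training (the cost is summed over
#'   pixels, so plain descent needs a learning rate inversely proportional
#'   to the image area and correspondingly many epochs).
#' @return list with `net` (best checkpoint), `log` (data.frame: epoch,
#'   total/data/decay cost, train_psnr, test_psnr).
#' @export
train_deep <- function(pairs, split = c(length(pairs), 0), epochs = 50,
                       net = conv_net(), batch_size = 8, shuffle_seed = 0,
                       optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  n_train <- split[1]; n_test <- split[2]
  if (n_train < 1) stop_invalid("need at least one training pair")
  if (n_train + n_test > length(pairs)) stop_invalid("split exceeds available pairs")
  tr <- pairs[seq_len(n_train)]
  te <- if (n_test > 0) pairs[n_train + seq_len(n_test)] else list()
  xs <- lapply(tr, `[[`, "x"); ys <- lapply(tr, `[[`, "y")
  log <- data.frame(epoch = integer(), total = numeric(), data = numeric(),
                    decay = numeric(), train_psnr = numeric(),
                    test_psnr = numeric())
  mean_psnr <- function(nn, pp) {
    if (!length(pp)) return(NA_real_)
    mean(vapply(pp, function(p)
      psnr(p$y, clip01(deep_forward(nn, p$x))), 0))
  }
  adam <- if (optimizer == "adam") adam_state(net) else NULL
  best <- net; best_score <- -Inf
  for (ep in seq_len(epochs)) {
    ord <- with_seed(shuffle_seed + ep, sample.int(n_train))
    for (start in seq(1, n_train, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1, n_train)]
      if (is.null(adam)) {
        net <- sgd_step(net, xs[sel], ys[sel])
      } else {
        st <- adam_step(net, adam, xs[sel], ys[sel])
        net <- st$net; adam <- st$state
      }
    }
    cst <- deep_cost(net, xs, ys)
    if (!is.finite(cst$total) || cst$total > 1e6)
      stop("training diverged (cost ", format(cst$total), ") at epoch ", ep)
    trp <- mean_psnr(net, tr); tep <- mean_psnr(net, te)
    log <- rbind(log, data.frame(epoch = ep, total = cst$total,
                                 data = cst$data, decay = cst$decay,
                                 train_psnr = trp, test_psnr = tep))
    score <- if (length(te)) tep else trp
    if (score > best_score) { best_score <- score; best <- net }
  }
  list(net = best, log = log)
}

#' @noRd
adam_state <- function(net) {
  list(t = 0,
       m = lapply(net$layers, function(l)
         list(w = array(0, dim(l$w)), b = numeric(length(l$b)))),
       v = lapply(net$layers, function(l)
         list(w = array(0, dim(l$w)), b = numeric(length(l$b)))))
}

#' adaptive-moment update on the same cost gradients as sgd_step
#' @noRd
adam_step <- function(net, state, xs, ys, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  g <- .deep_batch_grad_cpp(xs, ys, net$layers)
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  a <- net$learning_rate
  for (l in seq_along(net$layers)) {
    gw <- g$grad_w[[l]] + net$weight_decay * net$layers[[l]]$w
    gb <- g$grad_b[[l]]
    if (any(!is.finite(gw)) || any(!is.finite(gb)))
      stop("non-finite gradient encountered in layer ", l)
    state$m[[l]]$w <- beta1 * state$m[[l]]$w + (1 - beta1) * gw
    state$v[[l]]$w <- beta2 * state$v[[l]]$w + (1 - beta2) * gw^2
    state$m[[l]]$b <- beta1 * state$m[[l]]$b + (1 - beta1) * gb
    state$v[[l]]$b <- beta2 * state$v[[l]]$b + (1 - beta2) * gb^2
    net$layers[[l]]$w <- net$layers[[l]]$w -
      a * (state$m[[l]]$w / bc1) / (sqrt(state$v[[l]]$w / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      a * (state$m[[l]]$b / bc1) / (sqrt(state$v[[l]]$b / bc2) + eps)
  }
  list(net = net, state = state)
}

#' Deep-dictionary reconstruction of undersampled k-space
#'
#' Forward pass of a trained network on the zero-filled reconstruction,
#' followed (by default) by a data-consistency projection restoring the
#' measured k-space entries exactly. The network should have been trained
#' on the same mask family and sampling rate.
#'
#' @param sample a [kspace_sample].
#' @param net a trained [conv_net].
#' @param data_consistency apply the final projection (default `TRUE`).
#' @return the reconstructed image.
#' @export
reconstruct_deep <- function(sample, net, data_consistency = TRUE) {
  stopifnot(inherits(sample, "kspace_sample"))
  x <- zero_filled(sample)
  out <- deep_forward(net, x)
  if (isTRUE(data_consistency)) out <- .dc_project(out, sample)
  else out <- clip01(out)
  out
}
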