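#' Plan a method-by-sampling-rate benchmark
#'
#' Describes the full benchmark crossing a frozen phantom suite with a set
#' of sampling rates and reconstruction methods, the shape in which
#' accelerated-MRI comparisons are conventionally tabulated (method rows,
#' sampling-rate columns, PSNR/SSIM cells).
#'
#' @param n_phantoms suite size.
#' @param size phantom side in pixels.
#' @param rates sampling-rate grid (defaults to `c(0.3, 0.4, 0.5, 0.6)`;
#'   `c(0.2, 0.3, 0.4, 0.5)` is equally valid -- both grids appear in the
#'   benchmarking literature and neither is privileged here).
#' @param methods subset of `"zero_filled"`, `"tv"`, `"dict"`, `"deep"`.
#' @param mask_pattern sampling pattern for [mask_spec()].
#' @param noise_sigma k-space noise level per component.
#' @param phantom base [phantom_spec] for the suite (its seed is re-derived
#'   per phantom).
#' @param tv_lambda_grid candidate TV weights; the best on a held-out
#'   tuning phantom (per rate) is applied to the whole suite.
#' @param dict a [dict_recon_spec] for the synthetic-dictionary route.
#'   With `train = "corpus"` (the default here) one dictionary is learned
#'   per experiment from `n_corpus` extra training phantoms and reused for
#'   every cell, mirroring the train/test design of the deep route.
#' @param n_corpus number of training phantoms behind the corpus
#'   dictionary.
#' @param patch a [patch_config].
#' @param deep_layers,deep_lr,deep_decay,deep_epochs,deep_n_train,deep_optimizer
#'   architecture and training configuration of the deep route. The
#'   benchmark harness trains with the adaptive optimizer by default; the
#'   plain gradient-descent update remains the package default elsewhere.
#' @param seed master seed; every per-phantom, per-mask and training seed
#'   is derived from it and recorded in the manifest.
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_phantoms = 20, size = 64,
                            rates = c(0.3, 0.4, 0.5, 0.6),
                            methods = c("zero_filled", "tv", "dict", "deep"),
                            mask_pattern = "variable_density",
                            noise_sigma = 0.005,
                            phantom = phantom_spec(height = size, width = size,
                                                   texture_amp = 0.03),
                            tv_lambda_grid = 10^seq(-4, -1),
                            dict = dict_recon_spec(n_atoms = 256, T = 5,
                                                   learn_iters = 8,
                                                   refine_iters = 2,
                                                   outer_iters = 8,
                                                   train = "corpus"),
                            n_corpus = 12,
                            patch = patch_config(patch_size = 8, stride = 2),
                            deep_layers = list(c(9, 1, 24), c(1, 24, 12),
                                               c(5, 12, 1)),
                            deep_lr = 2e-3, deep_decay = 1e-6,
                            deep_epochs = 80, deep_n_train = 32,
                            deep_optimizer = "adam", seed = 0) {
  methods <- match.arg(methods, c("zero_filled", "tv", "dict", "deep"),
                       several.ok = TRUE)
  if (!length(rates)) stop_invalid("need at least one sampling rate")
  if (any(rates <= 0 | rates > 1)) stop_invalid("rates must lie in (0, 1]")
  structure(list(n_phantoms = as.integer(n_phantoms), size = as.integer(size),
                 rates = rates, methods = methods,
                 mask_pattern = mask_pattern, noise_sigma = noise_sigma,
                 phantom = phantom, tv_lambda_grid = tv_lambda_grid,
                 dict = dict, n_corpus = as.integer(n_corpus),
                 patch = patch, deep_layers = deep_layers,
                 deep_lr = deep_lr, deep_decay = deep_decay,
                 deep_epochs = deep_epochs,
                 deep_n_train = as.integer(deep_n_train),
                 deep_optimizer = deep_optimizer,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' @noRd
plan_phantom <- function(plan, index) {
  sp <- plan$phantom
  sp$seed <- plan$seed * 10000L + as.integer(index)
  make_phantom(sp)
}

#' Mask and noise seeds depend on the phantom but not on the rate: the
#' weighted sampling behind each pattern draws sequentially, so masks at
#' increasing rates are (up to symmetrization bookkeeping) nested, and the
#' rate sweep isolates the effect of the added samples instead of
#' re-randomizing the whole acquisition per rate.
#' @noRd
plan_sample <- function(plan, image, rate, index) {
  ms <- mask_spec(pattern = plan$mask_pattern, sampling_rate = rate,
                  seed = plan$seed * 10000L + 5000L + as.integer(index))
  m <- make_mask(ms, dim(image))
  simulate_acquisition(image, m, plan$noise_sigma,
                       seed = plan$seed * 10000L + 7000L + as.integer(index))
}

#' Run the benchmark
#'
#' For every (phantom, rate, method) cell: simulate the acquisition,
#' reconstruct, and score PSNR/SSIM against the ground-truth phantom.
#' The TV weight is tuned per rate on one extra phantom outside the scored
#' suite; the deep network is trained per rate on extra phantoms outside
#' the scored suite. Deterministic under the plan seed; all derived seeds
#' are reported in the manifest.
#'
#' @param plan an [experiment_plan].
#' @param verbose print per-cell progress.
#' @return list with `results` (long data.frame: method, rate, phantom,
#'   psnr_db, ssim), `summary` (mean and sd per method x rate), `manifest`
#'   (resolved parameters).
#' @export
run_experiment <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  suite <- lapply(seq_len(plan$n_phantoms), function(i) plan_phantom(plan, i))
  res <- list()
  tuned_lambda <- list()
  nets <- list()
  tune_img <- plan_phantom(plan, 900001L)
  dict_spec <- plan$dict
  if ("dict" %in% plan$methods && dict_spec$train == "corpus" &&
      is.null(dict_spec$dictionary)) {
    corpus <- lapply(seq_len(plan$n_corpus), function(i)
      plan_phantom(plan, 300000L + i))
    Yc <- do.call(cbind, lapply(corpus, function(im)
      extract_patches(im, plan$patch)$Y))
    dict_spec$dictionary <- learn_dictionary(
      Yc, dict_spec$n_atoms, dict_spec$T, dict_spec$learn_iters,
      dict_spec$seed)
  }
  for (rate in plan$rates) {
    rid <- sprintf("r%03d", round(1000 * rate))
    samples <- lapply(seq_len(plan$n_phantoms), function(i)
      plan_sample(plan, suite[[i]], rate, i))
    if ("tv" %in% plan$methods) {
      tune_s <- plan_sample(plan, tune_img, rate, 900001L)
      scores <- vapply(plan$tv_lambda_grid, function(lam) {
        r <- reconstruct_tv(tune_s, tv_solve_spec(lambda_tv = lam,
                                                  max_iters = 60))
        psnr(tune_img, r$image)
      }, 0)
      tuned_lambda[[rid]] <- plan$tv_lambda_grid[which.max(scores)]
    }
    if ("deep" %in% plan$methods) {
      pairs <- lapply(seq_len(plan$deep_n_train), function(i) {
        img <- plan_phantom(plan, 100000L + i)
        s <- plan_sample(plan, img, rate, 100000L + i)
        list(x = zero_filled(s), y = img)
      })
      net0 <- conv_net(plan$deep_layers, learning_rate = plan$deep_lr,
                       weight_decay = plan$deep_decay,
                       seed = plan$seed + 31L)
      fit <- train_deep(pairs, split = c(plan$deep_n_train, 0),
                        epochs = plan$deep_epochs, net = net0,
                        shuffle_seed = plan$seed + 17L,
                        optimizer = plan$deep_optimizer)
      nets[[rid]] <- fit$net
    }
    for (i in seq_len(plan$n_phantoms)) {
      truth <- suite[[i]]; s <- samples[[i]]
      for (m in plan$methods) {
        rec <- tryCatch(switch(m,
          zero_filled = zero_filled(s),
          tv = reconstruct_tv(s, tv_solve_spec(
            lambda_tv = tuned_lambda[[rid]], max_iters = 120))$image,
          dict = clip01(reconstruct_dict(s, plan$patch, dict_spec)$image),
          deep = clip01(reconstruct_deep(s, nets[[rid]]))),
          error = function(e) e)
        if (inherits(rec, "error")) {
          res[[length(res) + 1]] <- data.frame(
            method = m, rate = rate, phantom = i, psnr_db = NA_real_,
            ssim = NA_real_, error = conditionMessage(rec),
            stringsAsFactors = FALSE)
          next
        }
        res[[length(res) + 1]] <- data.frame(
          method = m, rate = rate, phantom = i,
          psnr_db = psnr(truth, rec), ssim = ssim(truth, rec),
          error = NA_character_, stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("rate %.2f phantom %d %s: PSNR %.2f SSIM %.4f",
                          rate, i, m, psnr(truth, rec), ssim(truth, rec)))
      }
    }
  }
  results <- do.call(rbind, res)
  summary <- stats::aggregate(cbind(psnr_db, ssim) ~ method + rate,
                              data = results, FUN = mean, na.rm = TRUE)
  sds <- stats::aggregate(cbind(psnr_db, ssim) ~ method + rate,
                          data = results, FUN = stats::sd)
  names(sds)[3:4] <- c("psnr_sd", "ssim_sd")
  summary <- merge(summary, sds, by = c("method", "rate"))
  summary <- summary[order(summary$method, summary$rate), ]
  manifest <- list(plan = unclass(plan), tuned_lambda = tuned_lambda,
                   r_version = R.version.string)
  list(results = results, summary = summary, manifest = manifest)
}

#' Training-set-size sweep for the deep route
#'
#' Trains the deep reconstructor at a fixed sampling rate with increasing
#' numbers of training pairs and scores mean test-set SSIM on a fixed
#' held-out suite, the standard learning-curve diagnostic.
#'
#' @param sizes increasing training-set sizes.
#' @param n_test held-out pairs.
#' @param rate sampling rate.
#' @param plan an [experiment_plan] carrying the phantom/mask/deep
#'   configuration.
#' @return data.frame with `n_train`, `test_ssim`, `test_psnr`.
#' @export
sweep_training_size <- function(sizes = c(10, 20, 40, 60), n_test = 10,
                                rate = 0.4, plan = experiment_plan()) {
  stopifnot(inherits(plan, "experiment_plan"))
  n_max <- max(sizes)
  all_pairs <- lapply(seq_len(n_max + n_test), function(i) {
    img <- plan_phantom(plan, 200000L + i)
    s <- plan_sample(plan, img, rate, 200000L + i)
    list(x = zero_filled(s), y = img)
  })
  test <- all_pairs[n_max + seq_len(n_test)]
  out <- lapply(sizes, function(n) {
    net0 <- conv_net(plan$deep_layers, learning_rate = plan$deep_lr,
                     weight_decay = plan$deep_decay, seed = plan$seed + 31L)
    fit <- train_deep(all_pairs[seq_len(n)], split = c(n, 0),
                      epochs = plan$deep_epochs, net = net0,
                      shuffle_seed = plan$seed + 17L,
                      optimizer = plan$deep_optimizer)
    sc <- vapply(test, function(p) {
      rec <- clip01(deep_forward(fit$net, p$x))
      c(ssim(p$y, rec), psnr(p$y, rec))
    }, c(0, 0))
    data.frame(n_train = n, test_ssim = mean(sc[1, ]),
               test_psnr = mean(sc[2, ]))
  })
  do.call(rbind, out)
}
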