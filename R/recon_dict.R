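#' Sparse-code one sample by orthogonal matching pursuit
#'
#' Greedy atom selection with orthogonal re-projection: after each pick the
#' coefficients are refit by least squares on the selected support, so the
#' residual is orthogonal to every selected atom and its norm is
#' non-increasing per step. `T = 0` returns the zero code.
#'
#' @param y numeric vector (one patch).
#' @param D dictionary matrix (`patch_dim x n_atoms`) with unit-norm atoms.
#' @param T maximum number of nonzeros (clipped to `n_atoms` with a warning
#'   if larger).
#' @return a sparse coefficient vector of length `n_atoms` (dense storage).
#' @export
omp_code <- function(y, D, T) {
  if (!is.matrix(D)) stop_invalid("D must be a matrix")
  if (length(y) != nrow(D)) stop_dim("sample length must match atom dimension")
  if (T > ncol(D)) {
    warning("T exceeds the number of atoms; clipped")
    T <- ncol(D)
  }
  as.vector(.omp_batch_cpp(D, matrix(y, ncol = 1), as.integer(T)))
}

#' Learn a synthetic patch dictionary (K-SVD style)
#'
#' Minimizes `||Y - D X||_F^2` subject to `||x_i||_0 <= T` by alternating
#' batch OMP sparse coding with sequential rank-1 refits of each atom on
#' its support (the exact minimizer of the restricted subproblem). New
#' codes are only accepted per column when they do not worsen that column's
#' residual, so the objective trace is non-increasing by construction.
#' Atoms that lose all support are re-seeded from the worst-represented
#' patches and renormalized.
#'
#' @param Y patch matrix (`patch_dim x n_patches`, `n_patches >= n_atoms`).
#' @param n_atoms dictionary size (default overcomplete, 4x the patch
#'   dimension is typical).
#' @param T per-patch sparsity target.
#' @param iters outer alternations (0 returns the initial dictionary with
#'   its OMP codes).
#' @param seed seed for the initialization (atoms drawn from random
#'   distinct training patches, normalized).
#' @param D_init optional warm-start dictionary (`patch_dim x n_atoms`);
#'   columns are renormalized. Overrides the data-driven initialization.
#' @return an object of class `patch_dictionary`: `atoms` (unit-norm
#'   columns), `sparsity_T`, `train_iters`, `seed`, plus the final `codes`
#'   and the `objective` trace (`iters + 1` values, the first being the
#'   objective of the initial dictionary).
#' @export
learn_dictionary <- function(Y, n_atoms = 4 * nrow(Y), T = 8, iters = 10,
                             seed = 0, D_init = NULL) {
  if (!is.matrix(Y) || ncol(Y) < 1) stop_invalid("Y must be a patch matrix")
  if (all(abs(Y) < 1e-14)) stop_invalid("degenerate all-zero patch matrix")
  if (ncol(Y) < n_atoms)
    stop_invalid("need at least as many patches as atoms")
  if (!is.null(D_init)) {
    if (!is.matrix(D_init) || nrow(D_init) != nrow(Y) ||
        ncol(D_init) != n_atoms)
      stop_invalid("D_init has the wrong shape")
    nrm <- sqrt(colSums(D_init^2))
    nrm[nrm < 1e-12] <- 1
    D0 <- sweep(D_init, 2, nrm, `/`)
  } else D0 <- init_dictionary(Y, n_atoms, seed)
  fit <- .ksvd_cpp(Y, D0, as.integer(T), as.integer(iters))
  structure(list(atoms = fit$D, sparsity_T = as.integer(T),
                 train_iters = as.integer(iters), seed = as.integer(seed),
                 codes = fit$X, objective = fit$objective),
            class = "patch_dictionary")
}

#' @noRd
init_dictionary <- function(Y, n_atoms, seed) {
  with_seed(seed, {
    nrg <- colSums(Y^2)
    cand <- order(runif(ncol(Y)))
    cand <- cand[nrg[cand] > 1e-12]
    D <- matrix(0, nrow(Y), n_atoms)
    take <- min(length(cand), n_atoms)
    if (take > 0) {
      sel <- Y[, cand[seq_len(take)], drop = FALSE]
      D[, seq_len(take)] <- sweep(sel, 2, sqrt(colSums(sel^2)), `/`)
    }
    if (take < n_atoms) { # fall back to random directions
      extra <- matrix(rnorm(nrow(Y) * (n_atoms - take)), nrow(Y))
      D[, (take + 1):n_atoms] <- sweep(extra, 2, sqrt(colSums(extra^2)), `/`)
    }
    D
  })
}

#' Configure the synthetic-dictionary reconstruction
#'
#' @param n_atoms dictionary size.
#' @param T per-patch sparsity.
#' @param learn_iters K-SVD alternations when the dictionary is (re)learned.
#' @param refine_iters cheaper alternations on later outer iterations.
#' @param outer_iters outer loops of (code, reassemble, enforce data
#'   consistency).
#' @param train `"self"` (learn from the current image's own patches, the
#'   default) or `"corpus"` (learn from external training images).
#' @param corpus list of training images when `train = "corpus"`.
#' @param dictionary optional pre-learned [patch_dictionary] for corpus
#'   mode, so one dictionary can be learned once and reused across many
#'   reconstructions.
#' @param seed initialization seed.
#' @return an object of class `dict_recon_spec`.
#' @export
dict_recon_spec <- function(n_atoms = 256, T = 8, learn_iters = 10,
                            refine_iters = 2, outer_iters = 3,
                            train = c("self", "corpus"), corpus = NULL,
                            dictionary = NULL, seed = 0) {
  train <- match.arg(train)
  if (!is.null(dictionary) && !inherits(dictionary, "patch_dictionary"))
    stop_invalid("dictionary must be a patch_dictionary")
  structure(list(n_atoms = as.integer(n_atoms), T = as.integer(T),
                 learn_iters = as.integer(learn_iters),
                 refine_iters = as.integer(refine_iters),
                 outer_iters = as.integer(outer_iters),
                 train = train, corpus = corpus, dictionary = dictionary,
                 seed = as.integer(seed)),
            class = "dict_recon_spec")
}

#' Replace sampled k-space entries of an image by the measured data
#'
#' The data-consistency projection: guarantees exact fidelity to the
#' acquisition on the sampled locations.
#'
#' @param image real image matrix.
#' @param sample a [kspace_sample].
#' @return real image whose transform equals the measurements on the mask.
#' @export
data_consistency <- function(image, sample) {
  .dc_project(image, sample)
}

#' @noRd
.dc_project <- function(image, sample) {
  stopifnot(inherits(sample, "kspace_sample"))
  k <- fft2c(image)
  k[sample$mask] <- sample$data[sample$mask]
  Re(ifft2c(k))
}

#' Synthetic-dictionary reconstruction of undersampled k-space
#'
#' Iterates: (1) extract patches from the current image (initially the
#' zero-filled inverse); (2) learn or refine a patch dictionary and sparse
#' approximation; (3) reassemble the sparse approximations by uniform
#' overlap averaging; (4) enforce data consistency by restoring the
#' measured k-space entries. After the final consistency step the sampled
#' entries of the output's transform equal the measurements exactly.
#'
#' @param sample a [kspace_sample].
#' @param cfg a [patch_config].
#' @param spec a [dict_recon_spec].
#' @return a list with `image`, `dictionary` (the final
#'   [patch_dictionary]), and `log` (objective traces per outer
#'   iteration).
#' @export
reconstruct_dict <- function(sample, cfg = patch_config(),
                             spec = dict_recon_spec()) {
  stopifnot(inherits(sample, "kspace_sample"), inherits(cfg, "patch_config"),
            inherits(spec, "dict_recon_spec"))
  x <- zero_filled(sample)
  dict <- NULL
  traces <- list()
  if (spec$train == "corpus") {
    if (!is.null(spec$dictionary)) {
      dict <- spec$dictionary
    } else {
      if (is.null(spec$corpus) || !length(spec$corpus))
        stop_invalid("corpus training requested but no corpus images given")
      Yc <- do.call(cbind, lapply(spec$corpus, function(im)
        extract_patches(im, cfg)$Y))
      dict <- learn_dictionary(Yc, spec$n_atoms, spec$T, spec$learn_iters,
                               spec$seed)
      traces$corpus <- dict$objective
    }
  }
  for (outer in seq_len(spec$outer_iters)) {
    pats <- extract_patches(x, cfg)
    if (spec$train == "self") {
      it <- if (outer == 1) spec$learn_iters else spec$refine_iters
      dict <- learn_dictionary(pats$Y, spec$n_atoms, spec$T, it, spec$seed,
                               D_init = if (outer > 1) dict$atoms else NULL)
      X <- dict$codes
      traces[[length(traces) + 1]] <- dict$objective
    } else {
      X <- .omp_batch_cpp(dict$atoms, pats$Y, spec$T)
    }
    approx <- dict$atoms %*% X
    x_d <- reassemble_patches(pats, approx)
    x <- data_consistency(x_d, sample)
  }
  list(image = x, dictionary = dict, log = list(objective = traces))
}
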