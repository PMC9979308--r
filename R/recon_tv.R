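#' Anisotropic total variation
#'
#' Discretization of the integral of `|dv/dx| + |dv/dy|`: the sum of
#' absolute forward differences along both axes with replicate (Neumann)
#' boundary, i.e. the last row/column contribute zero difference.
#' Nonnegative, zero iff the image is constant, and positively homogeneous
#' (`TV(c x) = |c| TV(x)`).
#'
#' @param image real image matrix.
#' @return a nonnegative scalar.
#' @export
tv_anisotropic <- function(image) {
  assert_image(image)
  d <- fwd_diff(image)
  sum(abs(d$dx)) + sum(abs(d$dy))
}

#' Smoothed (isotropic) total variation
#'
#' `sum(sqrt(dx^2 + dy^2 + phi^2))` over all pixels: the differentiable
#' relaxation of isotropic TV used inside the reconstruction objective.
#' The smoothing constant `phi` bounds the value below by
#' `n_pixels * phi` and above the un-smoothed TV by at most
#' `n_pixels * phi` (since `sqrt(a + phi^2) <= sqrt(a) + phi`).
#'
#' @inheritParams tv_anisotropic
#' @param phi positive smoothing constant.
#' @return a scalar `>= n_pixels * phi`.
#' @export
tv_smoothed <- function(image, phi) {
  assert_image(image)
  if (!is.numeric(phi) || phi <= 0) stop_invalid("phi must be positive")
  d <- fwd_diff(image)
  sum(sqrt(d$dx^2 + d$dy^2 + phi^2))
}

#' @noRd
fwd_diff <- function(v) {
  H <- nrow(v); W <- ncol(v)
  dx <- cbind(v[, -1, drop = FALSE] - v[, -W, drop = FALSE], rep(0, H))
  dy <- rbind(v[-1, , drop = FALSE] - v[-H, , drop = FALSE], rep(0, W))
  list(dx = dx, dy = dy)
}

#' gradient of tv_smoothed with respect to the image
#' @noRd
tv_smoothed_grad <- function(v, phi) {
  H <- nrow(v); W <- ncol(v)
  d <- fwd_diff(v)
  r <- sqrt(d$dx^2 + d$dy^2 + phi^2)
  gx <- d$dx / r; gy <- d$dy / r
  g <- -gx - gy
  g[, -1] <- g[, -1] + gx[, -W, drop = FALSE]
  g[-1, ] <- g[-1, ] + gy[-H, , drop = FALSE]
  g
}

#' Specify the TV reconstruction solve
#'
#' @param lambda_tv nonnegative regularization weight on the smoothed TV
#'   term.
#' @param phi positive TV smoothing constant (default 1e-3; small enough
#'   that the relaxation tracks true TV, large enough for stable
#'   gradients).
#' @param max_iters maximum gradient-descent iterations.
#' @param step_size initial step size for the backtracking line search.
#' @param tol relative-change stopping tolerance on the objective.
#' @return an object of class `tv_solve_spec`.
#' @export
tv_solve_spec <- function(lambda_tv = 1e-3, phi = 1e-3, max_iters = 100,
                          step_size = 1, tol = 1e-7) {
  if (lambda_tv < 0) stop_invalid("lambda_tv must be >= 0")
  if (phi <= 0) stop_invalid("phi must be > 0")
  if (max_iters < 1) stop_invalid("max_iters must be >= 1")
  if (step_size <= 0) stop_invalid("step_size must be > 0")
  structure(list(lambda_tv = lambda_tv, phi = phi,
                 max_iters = as.integer(max_iters),
                 step_size = step_size, tol = tol), class = "tv_solve_spec")
}

#' Total-variation-regularized compressed-sensing reconstruction
#'
#' Minimizes `||F_u x - y||_2^2 + lambda * TV_phi(x)` (data fidelity on the
#' sampled k-space entries plus smoothed total variation) by gradient
#' descent with a backtracking line search, initialized at the zero-filled
#' inverse. Backtracking enforces a monotonically non-increasing objective;
#' iterates are kept real (the imaging target is a real magnitude image)
#' and the final image is clipped to `[0, 1]`.
#'
#' @param sample a [kspace_sample].
#' @param spec a [tv_solve_spec].
#' @return a list with `image` (the reconstruction) and `log`, a list
#'   holding the per-iteration `objective`, accepted `step` sizes, and a
#'   `converged` flag (non-convergence within `max_iters` is reported in
#'   the log, not raised).
#' @export
reconstruct_tv <- function(sample, spec = tv_solve_spec()) {
  stopifnot(inherits(sample, "kspace_sample"), inherits(spec, "tv_solve_spec"))
  mask <- sample$mask; y <- sample$data
  x <- Re(ifft2c(y))
  objective <- function(x) {
    resid <- fft2c(x)
    resid[!mask] <- 0 + 0i
    resid <- resid - y
    sum(Mod(resid)^2) + spec$lambda_tv * tv_smoothed(x, spec$phi)
  }
  gradient <- function(x) {
    resid <- fft2c(x)
    resid[!mask] <- 0 + 0i
    resid <- resid - y
    2 * Re(ifft2c(resid)) + spec$lambda_tv * tv_smoothed_grad(x, spec$phi)
  }
  obj <- objective(x)
  objs <- obj; steps <- numeric(0)
  t0 <- spec$step_size
  converged <- FALSE
  for (it in seq_len(spec$max_iters)) {
    g <- gradient(x)
    gn2 <- sum(g^2)
    if (gn2 <= 1e-30) { converged <- TRUE; break }
    t <- t0
    accepted <- FALSE
    for (bt in 1:40) {
      xn <- x - t * g
      on <- objective(xn)
      if (on <= obj - 1e-4 * t * gn2) { accepted <- TRUE; break }
      t <- t / 2
    }
    if (!accepted) { converged <- TRUE; break } # gradient step cannot descend further
    rel <- (obj - on) / max(obj, 1e-30)
    x <- xn; obj <- on
    objs <- c(objs, obj); steps <- c(steps, t)
    t0 <- min(t * 2, spec$step_size * 4) # mild step recovery
    if (rel < spec$tol) { converged <- TRUE; break }
  }
  list(image = clip01(x),
       log = list(objective = objs, step = steps, converged = converged,
                  warning = if (!converged) "max_iters reached before tolerance" else NULL))
}
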