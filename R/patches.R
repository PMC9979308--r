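#' Patch extraction configuration
#'
#' @param patch_size square patch side in pixels.
#' @param stride step between patch origins; the final row/column of
#'   origins is clamped so the image border is always covered.
#' @param remove_mean subtract each patch's mean before coding (the
#'   dictionary then models texture; the DC component is restored at
#'   reassembly and anchored by k-space data consistency).
#' @return an object of class `patch_config`.
#' @export
patch_config <- function(patch_size = 8, stride = 2, remove_mean = TRUE) {
  if (stride < 1 || patch_size < stride)
    stop_invalid("need 1 <= stride <= patch_size")
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 remove_mean = isTRUE(remove_mean)), class = "patch_config")
}

#' @noRd
patch_origins <- function(extent, p, s) {
  n <- ceiling((extent - p) / s + 1)
  pmin(1 + (seq_len(n) - 1) * s, extent - p + 1)
}

#' Extract overlapping patches as a matrix
#'
#' Columns are vectorized `patch_size^2` patches in raster order (origins
#' advance along rows first, then down), `ceil((H-p)/s + 1) *
#' ceil((W-p)/s + 1)` of them, with the last row/column of origins clamped
#' to keep the border covered.
#'
#' @param image real image matrix, at least as large as the patch.
#' @param cfg a [patch_config].
#' @return a list with `Y` (patch matrix, one column per patch), `means`
#'   (per-patch means actually removed; zeros when `remove_mean` is off),
#'   and the geometry needed by [reassemble_patches()].
#' @export
extract_patches <- function(image, cfg) {
  assert_image(image)
  stopifnot(inherits(cfg, "patch_config"))
  H <- nrow(image); W <- ncol(image); p <- cfg$patch_size
  if (p > H || p > W) stop_invalid("patch larger than image")
  ro <- patch_origins(H, p, cfg$stride)
  co <- patch_origins(W, p, cfg$stride)
  # linear indices of one patch at origin (1,1), column-major
  base <- as.vector(outer(seq_len(p), (seq_len(p) - 1) * H, `+`))
  # origin offsets in raster order: cols vary fastest within a row of origins
  orig <- as.vector(t(outer(ro - 1, (co - 1) * H, `+`)))
  idx <- outer(base, orig, `+`)
  Y <- matrix(image[idx], nrow = p * p)
  means <- if (cfg$remove_mean) colMeans(Y) else numeric(ncol(Y))
  if (cfg$remove_mean) Y <- sweep(Y, 2, means)
  list(Y = Y, means = means, idx = idx, shape = c(H, W), cfg = cfg)
}

#' Reassemble an image from (approximated) patches
#'
#' Overlapping patches are combined by uniform averaging (each pixel is the
#' mean of all patch approximations covering it). With untouched patches
#' this inverts [extract_patches()] exactly.
#'
#' @param patches the geometry list returned by [extract_patches()].
#' @param Y optionally, a replacement patch matrix (e.g. the sparse
#'   approximation `D %*% X`); defaults to the extracted patches.
#' @return the reassembled image matrix.
#' @export
reassemble_patches <- function(patches, Y = NULL) {
  if (is.null(Y)) Y <- patches$Y
  if (patches$cfg$remove_mean) Y <- sweep(Y, 2, patches$means, `+`)
  v <- as.vector(Y)
  g <- as.vector(patches$idx)
  num <- rowsum(v, g)
  den <- rowsum(rep(1, length(g)), g)
  out <- numeric(prod(patches$shape))
  out[as.integer(rownames(num))] <- num / den
  matrix(out, patches$shape[1], patches$shape[2])
}
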