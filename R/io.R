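#' Read / write grayscale images
#'
#' Format is chosen by extension: PNG (via \pkg{png}), TIFF (via \pkg{tiff},
#' if installed) or NIfTI (via \pkg{RNifti}, if installed; first slice of a
#' volume). Multi-channel rasters are averaged to grayscale and intensities
#' normalized to `[0, 1]` on read; on write the image is clipped to
#' `[0, 1]`.
#'
#' @param path file path; extension selects the format.
#' @return `read_image()` returns a numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_invalid("TIFF support requires the 'tiff' package")
    a <- tiff::readTIFF(path)
  } else if (ext %in% c("nii", "gz")) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_invalid("NIfTI support requires the 'RNifti' package")
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) > 2) a <- a[, , 1]
    rng <- range(a)
    if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng)
  } else stop_invalid("unsupported image format: .", ext)
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  matrix(as.numeric(a), dim(a)[1], dim(a)[2])
}

#' @rdname read_image
#' @param image numeric matrix.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  img <- clip01(image)
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_invalid("TIFF support requires the 'tiff' package")
    tiff::writeTIFF(img, path)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_invalid("NIfTI support requires the 'RNifti' package")
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else stop_invalid("unsupported image format: .", ext)
  invisible(path)
}

#' Persist k-space records, dictionaries and network models
#'
#' Stored in R's portable binary serialization with a type tag and a config
#' echo, so a saved object can be inspected and reloaded reproducibly.
#'
#' @param object a `kspace_sample`, `patch_dictionary` or `conv_net`.
#' @param path file path (conventionally `.rds`).
#' @export
save_object <- function(object, path) {
  saveRDS(list(class = class(object)[1], object = object,
               dictmri_version = as.character(utils::packageVersion("dictmri"))),
          path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) {
  rec <- readRDS(path)
  rec$object
}
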