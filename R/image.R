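#' Validate a grayscale image matrix
#'
#' Images are plain integer matrices with values in `0..levels-1` (row =
#' image row). All pipeline stages operate on this representation; file IO
#' converts to and from it.
#'
#' @param img numeric matrix of integer-valued intensities.
#' @param levels number of gray levels `L`; intensities must lie in
#'   `[0, levels-1]`. Default 256 (8-bit).
#' @return the validated image as an integer matrix, invisibly usable
#'   downstream.
#' @export
as_gray_image <- function(img, levels = 256L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_schema("image must be a numeric matrix")
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop_degenerate("image must have at least one row and one column")
  }
  if (any(!is.finite(img))) stop_range("image contains non-finite values")
  if (any(img != floor(img))) stop_range("image intensities must be integers")
  if (any(img < 0) || any(img > levels - 1L)) {
    stop_range(sprintf("image intensities must lie in [0, %d]", levels - 1L))
  }
  storage.mode(img) <- "integer"
  img
}

#' Read an 8-bit single-channel PNG or TIFF image
#'
#' Multi-channel (RGB/RGBA) input is rejected: the pipeline is defined on
#' single-channel data and silent channel collapsing would change intensity
#' statistics.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return integer matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_config(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else {
      stop_schema(sprintf(
        "multi-channel image (%d channels) rejected; supply single-channel input",
        dim(x)[3]
      ))
    }
  }
  as_gray_image(round_half_up(x * 255), 256L)
}

#' Write a grayscale image as 8-bit PNG or TIFF
#'
#' @param img integer matrix in `[0, 255]`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  img <- as_gray_image(img, 256L)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_config(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_gray_image(mask * 255L, path)
}

# validate a 0/1 mask matrix
as_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop_schema("mask must be a numeric matrix")
  }
  if (!all(mask %in% c(0, 1))) stop_range("mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  mask
}
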