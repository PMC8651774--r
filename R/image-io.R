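#' Image frames
#'
#' An `rbc_frame` couples one 8-bit intensity raster (integer matrix, values
#' 0-255, row/column indexing with the origin at the top-left) with the
#' physical pixel scale in um/pixel, the unit every geometric quantity is
#' derived from, and a role tag (`pre_stress` / `post_stress`).
#'
#' @param pixels integer matrix (grayscale) or a 3-channel array (RGB) of
#'   values in 0-255.
#' @param pixel_scale um per pixel, > 0.
#' @param role `"pre_stress"`, `"post_stress"` or `"unknown"`.
#' @return an object of class `rbc_frame`.
#' @export
image_frame <- function(pixels, pixel_scale,
                        role = c("unknown", "pre_stress", "post_stress")) {
  role <- match.arg(role)
  stopifnot_scalar_pos(pixel_scale, "pixel_scale")
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    abort("pixels must be a matrix or a 3-channel array")
  if (min(pixels) < 0 || max(pixels) > 255)
    abort("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_scale = pixel_scale, role = role),
            class = "rbc_frame")
}

#' @export
print.rbc_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rbc_frame> %d x %d px @ %.3g um/px (%s)\n",
              d[1], d[2], x$pixel_scale, x$role))
  invisible(x)
}

#' Read an image file into an `rbc_frame`
#'
#' Reads 8-bit PNG or TIFF, grayscale or RGB (an alpha channel, if present,
#' is dropped). Intensities are returned on the 0-255 scale.
#'
#' @param path PNG or TIFF file.
#' @param pixel_scale um per pixel of the instrument that took the image.
#' @param role frame role tag.
#' @return an [image_frame()].
#' @export
read_image_frame <- function(path, pixel_scale,
                             role = c("unknown", "pre_stress", "post_stress")) {
  role <- match.arg(role)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(arr)) == 3 && dim(arr)[3] %in% c(2L, 4L))  # drop alpha
    arr <- arr[, , seq_len(dim(arr)[3] - 1L), drop = TRUE]
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1L) arr <- arr[, , 1L]
  arr <- round(arr * 255)
  if (is.matrix(arr)) arr <- matrix(as.integer(arr), nrow(arr), ncol(arr))
  image_frame(arr, pixel_scale, role)
}

#' Write an `rbc_frame` to an 8-bit PNG or TIFF
#'
#' @param frame an [image_frame()] (grayscale).
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image_frame <- function(frame, path) {
  px <- frame$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    abort(paste0("unsupported image format: .", ext))
  )
  invisible(path)
}
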