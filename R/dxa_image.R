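#' DXA image container
#'
#' A `dxa_image` is a numeric matrix of non-negative intensities in `[0, 1]`
#' with row 1 at the top (head end) of the scan, plus lightweight metadata.
#' All package coordinates are 1-based `(row, column)` pairs.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param image_id opaque identifier string.
#' @param pixel_size_mm optional positive pixel edge length in millimetres.
#' @return An object of class `dxa_image` (a matrix with attributes
#'   `image_id` and `pixel_size_mm`).
#' @examples
#' img <- dxa_image(matrix(runif(200), 20, 10), image_id = "toy")
#' dim(img)
#' @export
dxa_image <- function(pixels, image_id = "image", pixel_size_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L))
    stop_dxascol("invalid_input", "`pixels` must be a non-empty numeric matrix")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_dxascol("invalid_input", "intensities must be finite and non-negative")
  if (!is.null(pixel_size_mm) && (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0))
    stop_dxascol("invalid_input", "`pixel_size_mm` must be positive")
  structure(pixels,
            image_id = as.character(image_id)[1L],
            pixel_size_mm = pixel_size_mm,
            class = c("dxa_image", "matrix", "array"))
}

#' @export
print.dxa_image <- function(x, ...) {
  cat(sprintf("<dxa_image> %s: %d x %d px, intensity [%.3f, %.3f]\n",
              attr(x, "image_id"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @rdname dxa_image
#' @param x object to test.
#' @export
is_dxa_image <- function(x) inherits(x, "dxa_image")

#' Read a grayscale scan image
#'
#' Reads a PNG or TIFF file into a [dxa_image()]. Multi-channel images are
#' collapsed to their first channel; intensities are rescaled to `[0, 1]` by
#' the file bit depth (EBImage convention).
#'
#' @param path path to a PNG or TIFF file.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [dxa_image()].
#' @export
read_dxa <- function(path, image_id = NULL) {
  if (!file.exists(path))
    stop_dxascol("invalid_input", sprintf("image file not found: %s", path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) dat <- dat[, , 1L]
  # EBImage stores dim1 = x (screen columns); transpose to row-major anatomy
  dat <- t(dat)
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  dxa_image(pmax(dat, 0), image_id = image_id)
}

#' Write a scan image to disk
#'
#' TIFF output is written at 16 bits per sample; PNG at 8 bits (the maximum
#' the writer supports). Intensities are clipped to `[0, 1]`.
#'
#' @param image a [dxa_image()] or numeric matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_dxa <- function(image, path) {
  dat <- t(pmin(pmax(unclass(image), 0), 1))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(EBImage::Image(dat), path, bits.per.sample = 16L)
  } else if (ext == "png") {
    EBImage::writeImage(EBImage::Image(dat), path)
  } else {
    stop_dxascol("invalid_input", sprintf("unsupported image format: .%s", ext))
  }
  invisible(path)
}

#' @export
plot.dxa_image <- function(x, main = attr(x, "image_id"), ...) {
  m <- unclass(x)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), main = main, ...)
  invisible(x)
}
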