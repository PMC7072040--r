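#' Standardise image height preserving aspect ratio
#'
#' Isotropically rescales a scan to a common height, the first pipeline
#' stage: the output width is `round(width * target_height / height)`, so
#' the aspect ratio is preserved to within one pixel of rounding. Bilinear
#' interpolation is used for both down- and up-scaling. When the input is
#' already at the target height the image is returned unchanged
#' (idempotence).
#'
#' @param image a [dxa_image()] or numeric matrix.
#' @param target_height_px target height in pixels (>= 2); default taken
#'   from the `preprocessing.target_height_px` config key.
#' @return A [dxa_image()] of height `target_height_px`.
#' @examples
#' img <- dxa_image(matrix(runif(800 * 300), 800, 300))
#' dim(standardize_height(img, 400))  # 400 x 150
#' @export
standardize_height <- function(image,
                               target_height_px = dsm_config()$preprocessing$target_height_px) {
  if (!is_dxa_image(image)) image <- dxa_image(image)
  if (!is_scalar_num(target_height_px) || target_height_px < 2)
    stop_dxascol("invalid_input", "target_height_px must be >= 2")
  h <- nrow(image); w <- ncol(image)
  if (h == target_height_px) return(image)
  new_w <- max(1L, as.integer(round(w * target_height_px / h)))
  # dxa matrices are row-major anatomy; EBImage dim1 is x, so keep dim1 = rows
  out <- EBImage::resize(EBImage::Image(unclass(image)),
                         w = target_height_px, h = new_w, filter = "bilinear")
  dxa_image(pmax(EBImage::imageData(out), 0),
            image_id = attr(image, "image_id"),
            pixel_size_mm = if (!is.null(attr(image, "pixel_size_mm")))
              attr(image, "pixel_size_mm") * h / target_height_px)
}
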