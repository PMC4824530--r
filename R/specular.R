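# Specular highlight masking. Highlights on wet mucosa are saturated and
# desaturated; they move with the light source rather than the tissue, so
# features must never be seeded inside them. The reflection region is
# detected before registration with simple, configurable thresholds and a
# 2-px dilation.

#' Detect specular highlights
#'
#' Grayscale rule: intensity at or above `gray_thresh`. Color rule (h x w x 3
#' arrays): value at or above `value_thresh` with saturation at or below
#' `sat_thresh`. The raw mask is dilated by `dilate_px` pixels so that the
#' soft borders of highlights are excluded too. The detector is monotone:
#' brightening a pixel never removes it from the mask.
#'
#' @param image grayscale matrix or h x w x 3 color array (either \[0, 1\] or
#'   \[0, 255\] scale).
#' @param gray_thresh grayscale saturation threshold (gray levels).
#' @param value_thresh,sat_thresh HSV thresholds for color input.
#' @param dilate_px dilation radius in pixels.
#' @return logical matrix, `TRUE` on masked pixels.
#' @export
detect_specular_mask <- function(image, gray_thresh = 240,
                                 value_thresh = 230, sat_thresh = 0.15,
                                 dilate_px = 2) {
  if (is.array(image) && length(dim(image)) == 3) {
    img <- image
    if (max(img) <= 1 + 1e-12) img <- img * 255
    v <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
    mn <- pmin(img[, , 1], pmin(img[, , 2], img[, , 3]))
    s <- ifelse(v > 0, (v - mn) / v, 0)
    raw <- v >= value_thresh & s <= sat_thresh
  } else {
    img <- as_gray(image)
    raw <- img >= gray_thresh
  }
  if (!any(raw) || dilate_px <= 0) return(raw)
  brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  dil <- EBImage::dilate(raw * 1, brush)
  as.matrix(dil) > 0.5
}

#' Write a binary mask as a PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
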