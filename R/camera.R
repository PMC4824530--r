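# Lens distortion handling. Endoscopes carry wide-angle optics whose radial
# and tangential distortion must be rectified before feature detection. The
# model is the standard radial (k1, k2) + tangential (p1, p2) form used by
# planar-target calibration; the intrinsics are inputs (read from a config
# file), never estimated here.

#' Camera model with radial-tangential distortion
#'
#' @param fx,fy focal lengths in pixels (positive).
#' @param cx,cy principal point in pixels.
#' @param k1,k2 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, p1 = 0, p2 = 0) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, p1 = p1, p2 = p2),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera: f = (%.1f, %.1f) px, c = (%.1f, %.1f) px, k = (%g, %g), p = (%g, %g)\n",
              x$fx, x$fy, x$cx, x$cy, x$k1, x$k2, x$p1, x$p2))
  invisible(x)
}

#' Read a camera model from a flat YAML config
#'
#' Recognized keys: fx, fy, cx, cy, k1, k2, p1, p2 (distortion terms default
#' to 0).
#'
#' @param path YAML file.
#' @return a `camera_model`.
#' @export
read_camera <- function(path) {
  if (!file.exists(path)) stop("camera config not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("fx", "fy", "cx", "cy")
  if (!all(need %in% names(y))) {
    stop("camera config must define ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(names(y), c(need, "k1", "k2", "p1", "p2"))
  if (length(unknown)) {
    stop("unknown camera key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are fx, fy, cx, cy, k1, k2, p1, p2")
  }
  g <- function(k, d = 0) if (is.null(y[[k]])) d else as.numeric(y[[k]])
  camera_model(g("fx"), g("fy"), g("cx"), g("cy"),
               g("k1"), g("k2"), g("p1"), g("p2"))
}

# Forward distortion in normalized coordinates: ideal (x, y) -> distorted.
#' @keywords internal
distort_normalized <- function(cam, x, y) {
  r2 <- x^2 + y^2
  rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  xd <- x * rad + 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
  yd <- y * rad + cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
  cbind(xd, yd)
}

#' Apply lens distortion to ideal pixel coordinates
#'
#' The closed-form forward model: undistorted (ideal) pixel positions are
#' normalized by the intrinsics, distorted radially and tangentially, and
#' mapped back to pixels. This is the point mapper underlying the image
#' resampler.
#'
#' @param cam a `camera_model`.
#' @param pts n x 2 matrix of ideal pixel coordinates (0-based).
#' @return n x 2 matrix of distorted pixel coordinates.
#' @export
distort_points <- function(cam, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  x <- (pts[, 1] - cam$cx) / cam$fx
  y <- (pts[, 2] - cam$cy) / cam$fy
  d <- distort_normalized(cam, x, y)
  out <- cbind(d[, 1] * cam$fx + cam$cx, d[, 2] * cam$fy + cam$cy)
  dimnames(out) <- NULL
  out
}

#' Invert lens distortion for pixel coordinates
#'
#' Solves the inverse of the radial-tangential model by fixed-point
#' iteration, to below 1e-3 px residual. Points whose iteration does not
#' converge are returned as `NA` and counted in a warning.
#'
#' @param cam a `camera_model`.
#' @param pts n x 2 matrix of distorted pixel coordinates.
#' @param max_iter,tol iteration controls (tolerance in pixels).
#' @return n x 2 matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(cam, pts, max_iter = 30, tol = 1e-3) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  xd <- (pts[, 1] - cam$cx) / cam$fx
  yd <- (pts[, 2] - cam$cy) / cam$fy
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2
    x <- (xd - (2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2))) / rad
    y <- (yd - (cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y)) / rad
  }
  d <- distort_normalized(cam, x, y)
  res <- sqrt(((d[, 1] - xd) * cam$fx)^2 + ((d[, 2] - yd) * cam$fy)^2)
  bad <- !is.finite(res) | res > tol
  if (any(bad)) {
    warning(sum(bad), " point(s) did not converge below ", tol, " px")
    x[bad] <- NA; y[bad] <- NA
  }
  out <- cbind(x * cam$fx + cam$cx, y * cam$fy + cam$cy)
  dimnames(out) <- NULL
  out
}

#' Undistort an image
#'
#' Resamples the image so straight world lines map to straight image lines:
#' each output (ideal) pixel is looked up at its forward-distorted position
#' in the source with bilinear interpolation. Out-of-source pixels are set
#' to 0.
#'
#' @param image grayscale image.
#' @param cam a `camera_model`.
#' @return undistorted image of the same size.
#' @export
undistort_image <- function(image, cam) {
  image <- as_gray(image)
  h <- nrow(image); w <- ncol(image)
  if (identical(c(cam$k1, cam$k2, cam$p1, cam$p2), c(0, 0, 0, 0))) {
    return(image)                          # identity model, bit-exact
  }
  g <- as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
  src <- distort_points(cam, g)
  v <- sample_bilinear(image, src[, 1], src[, 2], outside = 0)
  matrix(v, h, w, byrow = TRUE)
}
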