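# Shared image conventions and numeric helpers.
#
# Images are numeric matrices with rows = image rows and columns = image
# columns, intensities on the 8-bit scale [0, 255]. Coordinates are 0-based:
# x is the column index (rightward), y the row index (downward), pixel centers
# at integers, so pixel (x, y) lives at img[y + 1, x + 1]. All modules share
# this convention.

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Coerce an image to a grayscale intensity matrix
#'
#' Accepts a numeric matrix (returned unchanged apart from scaling) or an
#' h x w x 3 array, which is converted with the luminance weights
#' 0.299 R + 0.587 G + 0.114 B. Inputs on \[0, 1\] (as returned by
#' [png::readPNG()]) are rescaled to the 8-bit range.
#'
#' @param image numeric matrix or 3-channel array.
#' @return numeric matrix with intensities in \[0, 255\].
#' @export
as_gray <- function(image) {
  if (is.array(image) && length(dim(image)) == 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix or an h x w x 3 array")
  }
  if (max(image) <= 1 + 1e-12) image <- image * 255
  image
}

# Bilinear sampling at 0-based subpixel coordinates. Returns `outside` for
# samples beyond the image domain [0, w-1] x [0, h-1].
#' @keywords internal
sample_bilinear <- function(img, x, y, outside = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  inside <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1 & is.finite(x) & is.finite(y)
  out <- rep(outside, length(x))
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  x0 <- clamp(floor(xi), 0, w - 2)
  y0 <- clamp(floor(yi), 0, h - 2)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
  out[inside] <- v
  out
}

# Deterministic sub-seed for a named random substream: all randomness in the
# package flows from one root seed through these. Kept below 2^31.
#' @keywords internal
sub_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003L
  as.integer((as.numeric(seed) %% 65011 + 1) * 30011 + h) %% 2147483629L
}

# Evaluate `expr` under a seeded RNG substream, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, name))
  expr
}

# Apply a 3x3 homography to 0-based points given as an n x 2 matrix.
#' @keywords internal
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' @keywords internal
is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

# Signed doubled area of a triangle given as a 3 x 2 matrix (0-based coords).
# Positive when vertices wind counter-clockwise in (x right, y down) axes.
#' @keywords internal
tri_area2 <- function(tri) {
  (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
    (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])
}
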