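# Planar geometry used by the patch machinery: Delaunay triangulation of the
# reference matches, exact affine homographies from triangle correspondences,
# barycentric interior points, incircle centers, and epipolar-line clipping.

#' Delaunay triangulation of a 2-D point set
#'
#' Thin wrapper around [interp::tri.mesh()] returning the triangulation as
#' an index matrix. Points are 0-based image coordinates.
#'
#' @param pts n x 2 numeric matrix of (x, y) points, n >= 3.
#' @return integer matrix with 3 columns; each row indexes one triangle's
#'   vertices in `pts`.
#' @export
delaunay_triangles <- function(pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (nrow(pts) < 3) stop("need at least 3 points to triangulate")
  # collinearity guard: deldir degenerates silently on collinear input
  cx <- pts[, 1] - mean(pts[, 1]); cy <- pts[, 2] - mean(pts[, 2])
  cross <- abs(cx * cy[1] - cy * cx[1])
  span <- max(abs(c(cx, cy)))
  if (span == 0 || all(cross < 1e-9 * span^2 + 1e-12)) {
    stop("all points are collinear; no triangulation exists")
  }
  tm <- interp::tri.mesh(pts[, 1], pts[, 2])
  tr <- interp::triangles(tm)
  if (nrow(tr) == 0) stop("triangulation failed (degenerate point set)")
  unname(tr[, 1:3, drop = FALSE])
}

#' Affine homography mapping one triangle onto another
#'
#' Returns the unique affine 3x3 matrix (last row 0, 0, 1) sending the three
#' source vertices exactly onto the three destination vertices.
#'
#' @param src,dst 3 x 2 matrices of triangle vertices (rows in correspondence).
#' @return 3 x 3 matrix `H` with `H %*% c(x, y, 1)` mapping source points.
#' @export
affine_from_triangles <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  A <- cbind(src, 1)
  if (abs(det(A)) < 1e-9) stop("degenerate source triangle")
  M <- solve(A, dst)                     # 3 x 2: columns are affine rows^T
  H <- rbind(t(M), c(0, 0, 1))
  dimnames(H) <- NULL
  H
}

#' Interior point of a triangle in barycentric coordinates
#'
#' Computes `s * v1 + t * v2 + (1 - s - t) * v3` for barycentric weights
#' constrained to the open triangle: `0 < s < 1`, `0 < t < 1`, `s + t < 1`.
#'
#' @param tri 3 x 2 matrix of vertices (v1, v2, v3 as rows).
#' @param s,t barycentric weights of v1 and v2.
#' @return length-2 numeric vector (x, y).
#' @export
barycentric_point <- function(tri, s, t) {
  if (!(s > 0 && s < 1 && t > 0 && t < 1 && s + t < 1)) {
    stop("barycentric weights must satisfy 0 < s < 1, 0 < t < 1, s + t < 1")
  }
  tri <- matrix(as.numeric(tri), ncol = 2)
  as.numeric(s * tri[1, ] + t * tri[2, ] + (1 - s - t) * tri[3, ])
}

#' Incircle center of a triangle
#'
#' The incenter `(a A + b B + c C) / (a + b + c)` with side lengths opposite
#' each vertex; HPFT's split point for patches that fail homographic
#' validation.
#'
#' @param tri 3 x 2 matrix of vertices.
#' @return length-2 numeric vector (x, y), strictly inside the triangle.
#' @export
incircle_center <- function(tri) {
  tri <- matrix(as.numeric(tri), ncol = 2)
  if (abs(tri_area2(tri)) < 1e-12) stop("degenerate triangle")
  a <- sqrt(sum((tri[2, ] - tri[3, ])^2))
  b <- sqrt(sum((tri[3, ] - tri[1, ])^2))
  c <- sqrt(sum((tri[1, ] - tri[2, ])^2))
  as.numeric((a * tri[1, ] + b * tri[2, ] + c * tri[3, ]) / (a + b + c))
}

# Barycentric weights of points relative to a triangle; returns n x 3 matrix.
#' @keywords internal
barycentric_weights <- function(tri, x, y) {
  d <- tri_area2(tri)
  w1 <- ((tri[2, 1] - x) * (tri[3, 2] - y) - (tri[3, 1] - x) * (tri[2, 2] - y)) / d
  w2 <- ((tri[3, 1] - x) * (tri[1, 2] - y) - (tri[1, 1] - x) * (tri[3, 2] - y)) / d
  cbind(w1, w2, 1 - w1 - w2)
}

# Integer pixels strictly inside a triangle (0-based coords). Returns a
# 2-column matrix of (x, y).
#' @keywords internal
pixels_in_triangle <- function(tri, eps = 1e-9) {
  xs <- seq(max(0, ceiling(min(tri[, 1]))), floor(max(tri[, 1])))
  ys <- seq(max(0, ceiling(min(tri[, 2]))), floor(max(tri[, 2])))
  if (length(xs) == 0 || length(ys) == 0) return(matrix(numeric(0), ncol = 2))
  g <- expand.grid(x = xs, y = ys)
  w <- barycentric_weights(tri, g$x, g$y)
  keep <- w[, 1] > eps & w[, 2] > eps & w[, 3] > eps
  as.matrix(g[keep, , drop = FALSE])
}

# Error-free variant used inside the registration loop: returns NULL both
# for the epipole case and for an empty intersection.
#' @keywords internal
epipolar_segment_safe <- function(Fmat, p, tri) {
  l <- as.numeric(Fmat %*% c(p[1], p[2], 1))
  nrm <- sqrt(l[1]^2 + l[2]^2)
  if (nrm < 1e-12) return(NULL)
  clip_line_to_triangle(l / nrm, tri)
}

#' Intersection of an epipolar line with a target triangle
#'
#' Clips the epipolar line of a reference point against the closed target
#' triangle, giving the segment along which HPFT searches for the match of a
#' patch's incircle center.
#'
#' @param F fundamental matrix (3 x 3) or an object with an `F` element.
#' @param p reference point (x, y).
#' @param tri 3 x 2 matrix: the target triangle.
#' @return 2 x 2 matrix with the segment endpoints as rows, or `NULL` when the
#'   line misses the triangle.
#' @export
epipolar_segment <- function(F, p, tri) {
  l <- epipolar_line(F, p)
  clip_line_to_triangle(l, tri)
}

# Clip the line a x + b y + c = 0 (a^2 + b^2 = 1) to a triangle by half-plane
# interval intersection along the line's parametrization.
#' @keywords internal
clip_line_to_triangle <- function(l, tri) {
  tri <- matrix(as.numeric(tri), ncol = 2)
  if (abs(tri_area2(tri)) < 1e-12) stop("degenerate triangle")
  a <- l[1]; b <- l[2]; c <- l[3]
  p0 <- c(-a * c, -b * c)              # foot of perpendicular from origin
  d <- c(-b, a)                        # unit direction
  tmin <- -Inf; tmax <- Inf
  # orient edges so the interior is on the negative side
  sgn <- if (tri_area2(tri) > 0) 1 else -1
  for (i in 1:3) {
    A <- tri[i, ]; B <- tri[i %% 3 + 1, ]
    e <- B - A
    n <- sgn * c(e[2], -e[1])          # outward normal
    num <- sum(n * (p0 - A))
    den <- sum(n * d)
    if (abs(den) < 1e-12) {
      if (num > 1e-9 * max(1, abs(c))) return(NULL)  # parallel, outside
    } else {
      t0 <- -num / den
      if (den > 0) tmax <- min(tmax, t0) else tmin <- max(tmin, t0)
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax) || tmin > tmax + 1e-12) return(NULL)
  rbind(p0 + tmin * d, p0 + tmax * d)
}

#' Normalized cross-correlation of a patch under its homography
#'
#' Rasterizes the integer pixels strictly inside the reference triangle,
#' samples the target image at their homography-mapped positions with
#' bilinear interpolation, and returns the zero-mean, unit-variance
#' normalized cross-correlation of the two intensity vectors. Values near 1
#' validate the locally-planar (homographic) hypothesis for the patch.
#'
#' @param img_ref,img_tgt grayscale images.
#' @param tri 3 x 2 reference triangle.
#' @param H 3 x 3 affine homography mapping reference to target coordinates.
#' @param mask_ref,mask_tgt optional logical matrices of pixels to exclude
#'   (specular highlights).
#' @param min_pixels minimum usable interior pixels.
#' @return correlation in \[-1, 1\], or `NA` when the patch cannot be
#'   validated (too few usable pixels or a flat intensity profile).
#' @export
patch_ncc <- function(img_ref, img_tgt, tri, H,
                      mask_ref = NULL, mask_tgt = NULL, min_pixels = 16) {
  px <- pixels_in_triangle(tri)
  if (nrow(px) < min_pixels) return(NA_real_)
  if (!is.null(mask_ref)) {
    keep <- !mask_ref[cbind(px[, 2] + 1, px[, 1] + 1)]
    px <- px[keep, , drop = FALSE]
  }
  if (nrow(px) < min_pixels) return(NA_real_)
  q <- apply_homography(H, px)
  a <- img_ref[cbind(px[, 2] + 1, px[, 1] + 1)]
  b <- sample_bilinear(img_tgt, q[, 1], q[, 2])
  if (!is.null(mask_tgt)) {
    qi <- cbind(clamp(round(q[, 2]), 0, nrow(img_tgt) - 1) + 1,
                clamp(round(q[, 1]), 0, ncol(img_tgt) - 1) + 1)
    b[mask_tgt[qi]] <- NA
  }
  ok <- !is.na(b)
  if (sum(ok) < min_pixels) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) < 1e-6 || stats::var(b) < 1e-6) return(NA_real_)
  stats::cor(a, b)
}
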