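# Epipolar geometry: fundamental-matrix estimation by the normalized
# eight-point algorithm inside a seeded RANSAC loop, and epipolar lines for
# the patch-center search.

# Hartley normalization: translate to the centroid, scale mean distance to
# sqrt(2). Returns the 3x3 similarity.
#' @keywords internal
norm_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Eight-point solve on >= 8 correspondences (rows of p1, p2), rank-2 enforced.
#' @keywords internal
eight_point <- function(p1, p2) {
  T1 <- norm_transform(p1); T2 <- norm_transform(p2)
  a <- apply_homography(T1, p1); b <- apply_homography(T2, p2)
  A <- cbind(b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1],
             b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2],
             a[, 1], a[, 2], 1)
  sv <- svd(A, nu = 0, nv = 9)
  F0 <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  s <- svd(F0)
  F0 <- s$u %*% diag(c(s$d[1], s$d[2], 0)) %*% t(s$v)
  F0 <- t(T2) %*% F0 %*% T1
  # unit Frobenius norm with a deterministic sign
  F0 <- F0 / sqrt(sum(F0^2))
  piv <- which.max(abs(F0))
  if (F0[piv] < 0) F0 <- -F0
  F0
}

#' Sampson distance of correspondences to a fundamental matrix
#'
#' First-order geometric error in pixels of each pair (m, m') against
#' m'^T F m = 0.
#'
#' @param F 3 x 3 fundamental matrix.
#' @param p1,p2 n x 2 matrices of reference and target points.
#' @return numeric vector of distances (px).
#' @export
sampson_distance <- function(F, p1, p2) {
  p1 <- cbind(matrix(as.numeric(p1), ncol = 2), 1)
  p2 <- cbind(matrix(as.numeric(p2), ncol = 2), 1)
  Fm <- p1 %*% t(F)                        # rows: F m
  Ftm <- p2 %*% F                          # rows: F^T m'
  num <- rowSums(p2 * Fm)
  den <- sqrt(Fm[, 1]^2 + Fm[, 2]^2 + Ftm[, 1]^2 + Ftm[, 2]^2)
  abs(num) / pmax(den, 1e-12)
}

#' Estimate the fundamental matrix from matches
#'
#' Normalized eight-point algorithm inside a seeded RANSAC loop (Sampson
#' distance inlier test), followed by a refit on the inliers with rank-2
#' enforcement and unit Frobenius norm. Downstream registration uses only
#' the inlier matches.
#'
#' @param matches an `hpft_matches` data.frame with at least 8 rows.
#' @param sampson_thresh inlier threshold in pixels.
#' @param max_iter RANSAC iteration cap (adaptive early stop at 0.99
#'   confidence).
#' @param seed integer seed; estimation is deterministic given it.
#' @return object of class `hpft_fundamental`: list with `F` (3 x 3, rank 2,
#'   unit Frobenius norm), `inlier_indices`, and `sampson` residuals for all
#'   input matches.
#' @export
estimate_fundamental <- function(matches, sampson_thresh = 1.5,
                                 max_iter = 2000, seed = 1) {
  p1 <- cbind(matches$x_ref, matches$y_ref)
  p2 <- cbind(matches$x_tgt, matches$y_tgt)
  n <- nrow(p1)
  if (n < 8) stop("degenerate geometry: fewer than 8 matches")
  best <- NULL; best_in <- integer(0); best_score <- Inf
  with_substream(seed, "ransac", {
    needed <- max_iter
    it <- 0
    while (it < min(needed, max_iter)) {
      it <- it + 1
      s <- sample.int(n, 8)
      Fh <- tryCatch(eight_point(p1[s, ], p2[s, ]), error = function(e) NULL)
      if (is.null(Fh)) next
      d <- sampson_distance(Fh, p1, p2)
      inl <- which(d < sampson_thresh)
      score <- sum(pmin(d, sampson_thresh))
      if (length(inl) > length(best_in) ||
          (length(inl) == length(best_in) && score < best_score)) {
        best <- Fh; best_in <- inl; best_score <- score
        w <- length(inl) / n
        if (w > 0) {
          needed <- min(max_iter,
                        ceiling(log(0.01) / log(max(1 - w^8, 1e-12))))
        }
      }
    }
  })
  if (length(best_in) < 8) stop("degenerate geometry: fewer than 8 inliers")
  for (pass in 1:2) {
    Fh <- eight_point(p1[best_in, , drop = FALSE], p2[best_in, , drop = FALSE])
    d <- sampson_distance(Fh, p1, p2)
    best_in <- which(d < sampson_thresh)
    if (length(best_in) < 8) stop("degenerate geometry: fewer than 8 inliers")
  }
  structure(list(F = Fh, inlier_indices = best_in, sampson = d),
            class = "hpft_fundamental")
}

#' @export
print.hpft_fundamental <- function(x, ...) {
  cat(sprintf("Fundamental matrix (rank 2): %d inliers, median Sampson %.3f px\n",
              length(x$inlier_indices),
              stats::median(x$sampson[x$inlier_indices])))
  invisible(x)
}

#' Epipolar line of a reference point
#'
#' Computes `l = F (x, y, 1)^T` scaled so that the line normal is unit
#' length (`a^2 + b^2 = 1`), i.e. `a x' + b y' + c` is the signed distance
#' of a target point to the line in pixels.
#'
#' @param F 3 x 3 fundamental matrix or an `hpft_fundamental`.
#' @param p reference point (x, y).
#' @return numeric (a, b, c).
#' @export
epipolar_line <- function(F, p) {
  if (inherits(F, "hpft_fundamental")) F <- F$F
  l <- as.numeric(F %*% c(p[1], p[2], 1))
  nrm <- sqrt(l[1]^2 + l[2]^2)
  if (nrm < 1e-12) stop("point maps to a zero epipolar line (epipole)")
  l / nrm
}
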