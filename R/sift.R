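# Interest point detection and description: a standard SIFT pipeline
# (difference-of-Gaussian extrema, orientation assignment, 4x4x8 gradient
# histogram) whose 128-element descriptor is pooled down to the 32-element
# form used throughout the registration (2x2 spatial pooling per orientation
# bin). Descriptors can also be computed at arbitrary points (patch incircle
# centers, epipolar-segment candidates), which are not DoG keypoints: there a
# fixed scale of 1.6 px is used with orientation assigned from the local
# gradient histogram.

# result[r, c] = m[r + dy, c + dx], `fill` outside.
#' @keywords internal
shift_mat <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  out[rs - dy, cs - dx] <- m[rs, cs]
  out
}

# Central-difference gradients, zero at borders.
#' @keywords internal
grad_xy <- function(G) {
  h <- nrow(G); w <- ncol(G)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (G[, 3:w] - G[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (G[3:h, ] - G[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' @keywords internal
build_pyramid <- function(img, n_octaves, n_scales, sigma0, assumed_blur = 0.5) {
  k <- 2^(1 / n_scales)
  base <- gblur_mat(img, sqrt(max(sigma0^2 - assumed_blur^2, 0.01)))
  octaves <- vector("list", n_octaves)
  for (o in seq_len(n_octaves)) {
    G <- vector("list", n_scales + 3)
    G[[1]] <- base
    sig <- sigma0 * k^(0:(n_scales + 2))
    for (i in 2:(n_scales + 3)) {
      G[[i]] <- gblur_mat(G[[i - 1]], sqrt(sig[i]^2 - sig[i - 1]^2))
    }
    octaves[[o]] <- G
    nxt <- G[[n_scales + 1]]               # blur 2 * sigma0
    base <- nxt[seq(1, nrow(nxt), 2), seq(1, ncol(nxt), 2)]
  }
  octaves
}

# 26-neighbor strict extrema of the DoG stack, with subpixel refinement and
# edge-response rejection. Returns per-keypoint octave coordinates.
#' @keywords internal
dog_keypoints <- function(D, n_scales, sigma0, contrast_thresh, edge_thresh) {
  h <- nrow(D[[1]]); w <- ncol(D[[1]])
  if (h < 12 || w < 12) return(NULL)
  res <- list()
  k <- 2^(1 / n_scales)
  thr <- contrast_thresh / n_scales        # per-layer threshold, as is standard
  for (l in 2:(n_scales + 1)) {
    nmax <- matrix(-Inf, h, w); nmin <- matrix(Inf, h, w)
    for (dl in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dl == 0 && dy == 0 && dx == 0) next
      s <- shift_mat(D[[l + dl]], dy, dx, NA)
      nmax <- pmax(nmax, s, na.rm = TRUE)
      nmin <- pmin(nmin, s, na.rm = TRUE)
    }
    cur <- D[[l]]
    cand <- (cur > nmax | cur < nmin) & abs(cur) > 0.5 * thr
    cand[c(1:5, (h - 4):h), ] <- FALSE
    cand[, c(1:5, (w - 4):w)] <- FALSE
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    r <- idx[, 1]; c <- idx[, 2]
    Dm <- D[[l - 1]]; Dc <- D[[l]]; Dp <- D[[l + 1]]
    v <- Dc[cbind(r, c)]
    gx <- (Dc[cbind(r, c + 1)] - Dc[cbind(r, c - 1)]) / 2
    gy <- (Dc[cbind(r + 1, c)] - Dc[cbind(r - 1, c)]) / 2
    gs <- (Dp[cbind(r, c)] - Dm[cbind(r, c)]) / 2
    dxx <- Dc[cbind(r, c + 1)] + Dc[cbind(r, c - 1)] - 2 * v
    dyy <- Dc[cbind(r + 1, c)] + Dc[cbind(r - 1, c)] - 2 * v
    dss <- Dp[cbind(r, c)] + Dm[cbind(r, c)] - 2 * v
    dxy <- (Dc[cbind(r + 1, c + 1)] - Dc[cbind(r + 1, c - 1)] -
              Dc[cbind(r - 1, c + 1)] + Dc[cbind(r - 1, c - 1)]) / 4
    dxs <- (Dp[cbind(r, c + 1)] - Dp[cbind(r, c - 1)] -
              Dm[cbind(r, c + 1)] + Dm[cbind(r, c - 1)]) / 4
    dys <- (Dp[cbind(r + 1, c)] - Dp[cbind(r - 1, c)] -
              Dm[cbind(r + 1, c)] + Dm[cbind(r - 1, c)]) / 4
    # closed-form 3x3 inverse (cofactors), vectorized over candidates
    det3 <- dxx * (dyy * dss - dys^2) - dxy * (dxy * dss - dys * dxs) +
      dxs * (dxy * dys - dyy * dxs)
    ok <- abs(det3) > 1e-12
    i11 <- (dyy * dss - dys^2) / det3
    i12 <- -(dxy * dss - dxs * dys) / det3
    i13 <- (dxy * dys - dxs * dyy) / det3
    i22 <- (dxx * dss - dxs^2) / det3
    i23 <- -(dxx * dys - dxy * dxs) / det3
    i33 <- (dxx * dyy - dxy^2) / det3
    ox <- -(i11 * gx + i12 * gy + i13 * gs)
    oy <- -(i12 * gx + i22 * gy + i23 * gs)
    os <- -(i13 * gx + i23 * gy + i33 * gs)
    val <- v + 0.5 * (gx * ox + gy * oy + gs * os)
    tr2 <- (dxx + dyy)^2
    dt <- dxx * dyy - dxy^2
    edge_ok <- dt > 0 & tr2 / dt < (edge_thresh + 1)^2 / edge_thresh
    keep <- ok & abs(ox) < 0.75 & abs(oy) < 0.75 & abs(os) < 0.75 &
      abs(val) >= thr & edge_ok
    if (!any(keep)) next
    res[[length(res) + 1]] <- data.frame(
      xo = c[keep] - 1 + ox[keep],
      yo = r[keep] - 1 + oy[keep],
      layer = l,
      sigma_rel = sigma0 * k^(l - 1 + os[keep])
    )
  }
  if (length(res) == 0) NULL else do.call(rbind, res)
}

# Dominant gradient orientation(s) at octave coordinates. Returns, per input
# point, a list of orientations (radians); `max_peaks` bounds how many.
#' @keywords internal
assign_orientations <- function(gx, gy, xo, yo, sigma_rel, max_peaks = 2) {
  m <- .orientation_batch(gx, gy, as.numeric(xo), as.numeric(yo),
                          as.numeric(sigma_rel), as.integer(max_peaks))
  lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v[!is.na(v)]
  })
}

# Plain-R reference implementation of the orientation histogram, kept as a
# cross-check for the compiled kernel.
#' @keywords internal
assign_orientations_ref <- function(gx, gy, xo, yo, sigma_rel, max_peaks = 2) {
  h <- nrow(gx); w <- ncol(gx)
  n <- length(xo)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sw <- 1.5 * sigma_rel[i]
    R <- max(2, round(3 * sw))
    c0 <- clamp(round(xo[i]) - R, 0, w - 1); c1 <- clamp(round(xo[i]) + R, 0, w - 1)
    r0 <- clamp(round(yo[i]) - R, 0, h - 1); r1 <- clamp(round(yo[i]) + R, 0, h - 1)
    sgx <- gx[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)]
    sgy <- gy[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)]
    X <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1)
    Y <- matrix(rep(r0:r1, c1 - c0 + 1), r1 - r0 + 1)
    wgt <- exp(-((X - xo[i])^2 + (Y - yo[i])^2) / (2 * sw^2))
    mag <- sqrt(sgx^2 + sgy^2) * wgt
    ang <- atan2(sgy, sgx) %% (2 * pi)
    b <- floor(ang / (2 * pi) * 36) %% 36
    full <- numeric(36)
    agg <- rowsum(as.numeric(mag), as.integer(b))
    full[as.integer(rownames(agg)) + 1] <- agg[, 1]
    # circular smoothing, two passes
    for (p in 1:2) {
      full <- (c(full[36], full[-36]) + full + c(full[-1], full[1])) / 3
    }
    mx <- max(full)
    if (mx <= 0) { out[[i]] <- 0; next }
    peaks <- which(full >= 0.8 * mx &
                     full > c(full[36], full[-36]) &
                     full >= c(full[-1], full[1]))
    if (length(peaks) == 0) peaks <- which.max(full)
    peaks <- peaks[order(full[peaks], decreasing = TRUE)]
    peaks <- peaks[seq_len(min(max_peaks, length(peaks)))]
    th <- vapply(peaks, function(pk) {
      l <- full[(pk - 2) %% 36 + 1]; cmid <- full[pk]; r <- full[pk %% 36 + 1]
      den <- l - 2 * cmid + r
      off <- if (abs(den) > 1e-12) 0.5 * (l - r) / den else 0
      ((pk - 1 + off + 0.5) / 36 * 2 * pi) %% (2 * pi)
    }, 0)
    out[[i]] <- th
  }
  out
}

# Batch 128-element descriptors from gradient fields, one row per keypoint.
# Layout: element index = (row_cell * 4 + col_cell) * 8 + orientation_bin,
# row/col cells indexed 0..3 in the keypoint's rotated frame. The compiled
# kernel carries the volume; descriptors_from_gradients_ref is the plain-R
# reference implementation of the same accumulation, kept as a cross-check.
#' @keywords internal
descriptors_from_gradients <- function(gx, gy, xo, yo, sigma_rel, theta) {
  .desc128_batch(gx, gy, as.numeric(xo), as.numeric(yo),
                 as.numeric(sigma_rel), as.numeric(theta))
}

#' @keywords internal
descriptors_from_gradients_ref <- function(gx, gy, xo, yo, sigma_rel, theta) {
  n <- length(xo)
  grid <- expand.grid(i = 0:15, j = 0:15)
  uc <- (grid$i - 7.5) / 4                 # column offset, cell units
  vc <- (grid$j - 7.5) / 4                 # row offset, cell units
  win <- exp(-(uc^2 + vc^2) / (2 * 2^2))   # Gaussian window, sigma = 2 cells
  ns <- length(uc)
  wc <- 3 * sigma_rel                      # cell width in pixels
  upx <- outer(wc, uc); vpx <- outer(wc, vc)       # n x ns
  ct <- cos(theta); st <- sin(theta)
  X <- xo + ct * upx - st * vpx
  Y <- yo + st * upx + ct * vpx
  sgx <- sample_bilinear(gx, as.numeric(X), as.numeric(Y), outside = 0)
  sgy <- sample_bilinear(gy, as.numeric(X), as.numeric(Y), outside = 0)
  mag <- sqrt(sgx^2 + sgy^2) * rep(win, each = n)
  ang <- (atan2(sgy, sgx) - rep(theta, ns)) %% (2 * pi)
  ob <- ang / (2 * pi) * 8
  xb <- rep(uc, each = n) + 1.5
  yb <- rep(vc, each = n) + 1.5
  kp <- rep(seq_len(n), ns)
  x0 <- floor(xb); y0 <- floor(yb); o0 <- floor(ob)
  fx <- xb - x0; fy <- yb - y0; fo <- ob - o0
  # trilinear scatter of all 8 corner contributions in one pass
  xc <- c(x0, x0 + 1, x0, x0 + 1, x0, x0 + 1, x0, x0 + 1)
  yc <- c(y0, y0, y0 + 1, y0 + 1, y0, y0, y0 + 1, y0 + 1)
  oc <- c(o0, o0, o0, o0, o0 + 1, o0 + 1, o0 + 1, o0 + 1)
  wz <- c(mag * (1 - fx) * (1 - fy) * (1 - fo),
          mag * fx * (1 - fy) * (1 - fo),
          mag * (1 - fx) * fy * (1 - fo),
          mag * fx * fy * (1 - fo),
          mag * (1 - fx) * (1 - fy) * fo,
          mag * fx * (1 - fy) * fo,
          mag * (1 - fx) * fy * fo,
          mag * fx * fy * fo)
  kp8 <- rep(kp, 8)
  valid <- xc >= 0 & xc <= 3 & yc >= 0 & yc <= 3 & wz > 0
  desc <- matrix(0, 128, n)
  if (any(valid)) {
    bin <- (yc[valid] * 4 + xc[valid]) * 8 + (oc[valid] %% 8)
    li <- (kp8[valid] - 1) * 128 + bin + 1
    s <- rowsum(wz[valid], li)
    desc[as.integer(rownames(s))] <- s[, 1]
  }
  d <- t(desc)
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d <- d / nrm
  d <- pmin(d, 0.2)                        # illumination clamp
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d / nrm
}

#' Pool a 128-element SIFT descriptor down to 32 elements
#'
#' Sums each 2x2 block of the 4x4 spatial cells separately per orientation
#' bin (2 x 2 x 8 = 32 values) and L2-normalizes, preserving SIFT's rotation
#' behavior while quartering the descriptor length.
#'
#' @param desc128 numeric vector of length 128 (the standard 4x4x8 layout,
#'   element index `(row_cell * 4 + col_cell) * 8 + orientation`), or a
#'   matrix with 128 columns (one descriptor per row).
#' @return vector of length 32 (or matrix with 32 columns), L2-normalized
#'   per descriptor.
#' @export
simplify_descriptor <- function(desc128) {
  if (is.matrix(desc128)) {
    if (ncol(desc128) != 128) stop("descriptors must have 128 columns")
    m <- desc128
  } else {
    if (length(desc128) != 128) stop("descriptor must have length 128")
    m <- matrix(desc128, 1, 128)
  }
  e <- 0:127
  iy <- e %/% 32; ix <- (e %/% 8) %% 4; io <- e %% 8
  pooled_bin <- ((iy %/% 2) * 2 + (ix %/% 2)) * 8 + io
  out <- matrix(0, nrow(m), 32)
  for (b in 0:31) {
    out[, b + 1] <- rowSums(m[, which(pooled_bin == b), drop = FALSE])
  }
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out <- out / nrm
  if (!is.matrix(desc128)) out <- as.numeric(out)
  out
}

#' Squared-difference distance between two 32-element descriptors
#'
#' The sum over the 32 elements of the squared differences (no square root),
#' the quantity V used by the candidate-selection rules. On L2-normalized
#' inputs it equals `2 - 2 * sum(a * b)` and ranges over \[0, 4\].
#'
#' @param a,b descriptors of equal length.
#' @return non-negative scalar.
#' @export
descriptor_distance <- function(a, b) {
  if (length(a) != length(b)) stop("descriptors must have equal length")
  sum((a - b)^2)
}

#' Detect SIFT features
#'
#' Standard SIFT keypoints (difference-of-Gaussian extrema with subpixel
#' refinement, edge-response rejection and gradient-histogram orientation
#' assignment), described by the 32-element simplified descriptor. Keypoints
#' inside the specular mask are discarded. When more than `budget` features
#' are found, a seeded uniform random subset of size `budget` is returned.
#'
#' @param image grayscale image.
#' @param mask optional logical matrix; `TRUE` pixels are excluded.
#' @param budget maximum number of features returned (at least 4).
#' @param seed integer seed for the budget subsampling.
#' @param n_scales DoG scales per octave.
#' @param sigma0 base blur of the scale space in pixels.
#' @param contrast_thresh DoG contrast threshold (intensities on \[0, 1\];
#'   applied per layer as `contrast_thresh / n_scales`, the usual convention).
#' @param edge_thresh principal-curvature ratio bound.
#' @return object of class `hpft_features`: list with `points`
#'   (data.frame `x`, `y`, `scale`, `orientation`) and `desc`
#'   (n x 32 matrix of L2-normalized descriptors).
#' @export
detect_features <- function(image, mask = NULL, budget = Inf, seed = 1,
                            n_scales = 3, sigma0 = 1.6,
                            contrast_thresh = 0.04, edge_thresh = 10) {
  image <- as_gray(image)
  if (budget < 4) stop("budget must be at least 4")
  img <- image / 255
  n_oct <- max(1, floor(log2(min(dim(img)) / 16)))
  pyr <- build_pyramid(img, n_oct, n_scales, sigma0)
  pts <- list(); descs <- list()
  for (o in seq_len(n_oct)) {
    G <- pyr[[o]]
    D <- lapply(1:(n_scales + 2), function(i) G[[i + 1]] - G[[i]])
    kp <- dog_keypoints(D, n_scales, sigma0, contrast_thresh, edge_thresh)
    if (is.null(kp)) next
    scale_mul <- 2^(o - 1)
    for (l in sort(unique(kp$layer))) {
      sel <- kp[kp$layer == l, , drop = FALSE]
      g <- grad_xy(G[[l]])
      oris <- assign_orientations(g$gx, g$gy, sel$xo, sel$yo, sel$sigma_rel)
      reps <- lengths(oris)
      xo <- rep(sel$xo, reps); yo <- rep(sel$yo, reps)
      sr <- rep(sel$sigma_rel, reps); th <- unlist(oris)
      d128 <- descriptors_from_gradients(g$gx, g$gy, xo, yo, sr, th)
      pts[[length(pts) + 1]] <- data.frame(
        x = xo * scale_mul, y = yo * scale_mul,
        scale = sr * scale_mul, orientation = th)
      descs[[length(descs) + 1]] <- simplify_descriptor(d128)
    }
  }
  if (length(pts) == 0) stop("untextured input: no features detected")
  points <- do.call(rbind, pts)
  desc <- do.call(rbind, descs)
  if (!is.null(mask)) {
    h <- nrow(image); w <- ncol(image)
    mi <- cbind(clamp(round(points$y), 0, h - 1) + 1,
                clamp(round(points$x), 0, w - 1) + 1)
    keep <- !mask[mi]
    points <- points[keep, , drop = FALSE]
    desc <- desc[keep, , drop = FALSE]
  }
  if (nrow(points) < 4) stop("untextured input: fewer than 4 features")
  if (nrow(points) > budget) {
    sel <- with_substream(seed, "budget",
                          sort(sample.int(nrow(points), budget)))
    points <- points[sel, , drop = FALSE]
    desc <- desc[sel, , drop = FALSE]
  }
  rownames(points) <- NULL
  structure(list(points = points, desc = desc,
                 image_dim = dim(image)), class = "hpft_features")
}

#' @export
print.hpft_features <- function(x, ...) {
  cat(sprintf("%d SIFT-32 features (scales %.2f-%.2f px)\n",
              nrow(x$points), min(x$points$scale), max(x$points$scale)))
  invisible(x)
}

# Precomputed gradient context for descriptors at arbitrary points: the image
# blurred to the fixed working scale once per registration.
#' @keywords internal
sift_context <- function(image, sigma = 1.6) {
  img <- as_gray(image) / 255
  G <- gblur_mat(img, sqrt(max(sigma^2 - 0.25, 0.01)))
  g <- grad_xy(G)
  list(gx = g$gx, gy = g$gy, sigma_rel = sigma)
}

#' Compute 32-element descriptors at arbitrary image points
#'
#' For points that are not DoG keypoints (patch incircle centers, candidates
#' along an epipolar segment) the descriptor is computed at a fixed scale of
#' `sigma` pixels with orientation assigned from the local gradient
#' histogram.
#'
#' @param image grayscale image, or a context previously built from one.
#' @param pts n x 2 matrix of (x, y) points.
#' @param sigma working scale in pixels.
#' @return n x 32 matrix of descriptors.
#' @export
descriptors_at <- function(image, pts, sigma = 1.6) {
  ctx <- if (is.list(image) && !is.null(image$gx)) image else sift_context(image, sigma)
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(pts)
  oris <- assign_orientations(ctx$gx, ctx$gy, pts[, 1], pts[, 2],
                              rep(ctx$sigma_rel, n), max_peaks = 1)
  th <- vapply(oris, `[`, 0, 1)
  d128 <- descriptors_from_gradients(ctx$gx, ctx$gy, pts[, 1], pts[, 2],
                                     rep(ctx$sigma_rel, n), th)
  simplify_descriptor(d128)
}
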