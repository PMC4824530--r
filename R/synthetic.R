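# Seeded synthetic-scene generator. Emulates the imaging conditions of
# textured, smoothly curved internal surfaces seen under viewpoint change:
# band-limited texture, piecewise-planar warps with exact ground truth,
# additive Gaussian noise, and saturated specular highlight blobs. Every
# generator is a pure function of its arguments (including the seed), so the
# whole algorithmic stack is testable without any real endoscopy data.

#' @keywords internal
gblur_mat <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

#' Generate a band-limited random texture
#'
#' Gaussian-smoothed white noise (sigma 2 px) min-max scaled into \[20, 235\]
#' minus headroom for a linear shading gradient. The construction guarantees
#' dense local contrast (every 64 x 64 tile has intensity standard deviation
#' well above 10 gray levels) so that SIFT finds interest points everywhere,
#' while leaving the top of the 8-bit range free for specular saturation.
#'
#' @param width,height image size in pixels, each at least 64.
#' @param seed integer seed; identical arguments give bit-identical images.
#' @return integer-valued intensity matrix (`height` x `width`) in \[0, 255\].
#' @export
generate_textured_plane <- function(width, height, seed = 1) {
  if (width < 64 || height < 64) stop("width and height must be at least 64")
  with_substream(seed, "texture", {
    n <- matrix(stats::rnorm(height * width), height, width)
    n <- gblur_mat(n, 2)
    n <- (n - min(n)) / (max(n) - min(n))
    ang <- stats::runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq(0, 1, length.out = width), each = height), height, width)
    gy <- matrix(rep(seq(0, 1, length.out = height), width), height, width)
    g <- cos(ang) * gx + sin(ang) * gy
    g <- (g - min(g)) / (max(g) - min(g))
    round(20 + 185 * n + 30 * g)
  })
}

#' @keywords internal
new_scene <- function(reference, target, truth_map, patch_truth,
                      noise_sigma, seed) {
  structure(list(reference = reference, target = target,
                 truth_map = truth_map, patch_truth = patch_truth,
                 noise_sigma = noise_sigma, seed = seed),
            class = "hpft_scene")
}

#' @export
print.hpft_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d, %d ground-truth patch(es), noise sigma %.1f, seed %d\n",
              ncol(x$reference), nrow(x$reference), length(x$patch_truth),
              x$noise_sigma, x$seed))
  invisible(x)
}

# Dense truth map (h x w x 2 array of target coordinates per reference pixel,
# NA where the reference pixel is not visible in the target frame).
#' @keywords internal
truth_map_from_fun <- function(w, h, map_fun) {
  g <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  q <- map_fun(as.matrix(g))
  vis <- q[, 1] >= 0 & q[, 1] <= w - 1 & q[, 2] >= 0 & q[, 2] <= h - 1
  q[!vis, ] <- NA
  tm <- array(NA_real_, c(h, w, 2))
  tm[, , 1] <- matrix(q[, 1], h, w, byrow = TRUE)
  tm[, , 2] <- matrix(q[, 2], h, w, byrow = TRUE)
  tm
}

#' Warp a texture through a single homography
#'
#' Produces a scene whose target is the texture resampled through `H`
#' (bilinear, out-of-source pixels black) plus optional zero-mean Gaussian
#' noise. The dense truth map is exactly the `H` mapping, and the single
#' ground-truth patch covers the full frame.
#'
#' @param texture grayscale reference image.
#' @param H invertible 3 x 3 matrix mapping reference to target coordinates.
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @param seed integer seed for the noise realization.
#' @return an `hpft_scene`.
#' @export
warp_scene <- function(texture, H, noise_sigma = 0, seed = 1) {
  texture <- as_gray(texture)
  if (abs(det(H)) < 1e-12) stop("H must be invertible")
  h <- nrow(texture); w <- ncol(texture)
  Hi <- solve(H)
  g <- as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
  src <- apply_homography(Hi, g)
  v <- sample_bilinear(texture, src[, 1], src[, 2], outside = 0)
  tgt <- matrix(v, h, w, byrow = TRUE)
  if (noise_sigma > 0) {
    tgt <- tgt + with_substream(seed, "warp_noise",
                                matrix(stats::rnorm(h * w, 0, noise_sigma), h, w))
  }
  tgt <- round(clamp(tgt, 0, 255))
  corners <- matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1),
                    ncol = 2, byrow = TRUE)
  tm <- truth_map_from_fun(w, h, function(p) apply_homography(H, p))
  new_scene(texture, tgt, tm, list(list(polygon = corners, H = H)),
            noise_sigma, seed)
}

# A mild random affine about the frame center: rotation within +/- 5 degrees,
# scale within +/- 5 %, translation within +/- 10 px. These magnitudes emulate
# the inter-frame viewpoint change of a slowly moving endoscope.
#' @keywords internal
random_base_affine <- function(w, h) {
  th <- stats::runif(1, -5, 5) * pi / 180
  sc <- stats::runif(1, 0.95, 1.05)
  tr <- stats::runif(2, -10, 10)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  R <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t0 <- c(cx, cy) - R %*% c(cx, cy) + tr
  rbind(cbind(R, t0), c(0, 0, 1))
}

# Recursively split the frame rectangle into `n` triangles without hanging
# nodes: an interior edge is always split on both sides (+2 triangles), a
# boundary edge on its single side (+1), so that every vertex is shared by
# all incident triangles and a continuous piecewise-affine map results from
# free per-vertex displacements.
#' @keywords internal
split_frame_triangles <- function(w, h, n) {
  verts <- matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1),
                  ncol = 2, byrow = TRUE)
  tris <- list(c(1L, 2L, 3L), c(1L, 3L, 4L))
  on_boundary <- function(p, q) {
    (p[1] == 0 && q[1] == 0) || (p[1] == w - 1 && q[1] == w - 1) ||
      (p[2] == 0 && q[2] == 0) || (p[2] == h - 1 && q[2] == h - 1)
  }
  tri_edges <- function(tr) list(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
  edge_len <- function(e) sqrt(sum((verts[e[1], ] - verts[e[2], ])^2))
  split_at <- function(ti, e) {
    # split triangle ti (and any other triangle sharing edge e) at a point on e
    u <- stats::runif(1, 0.4, 0.6)
    m <- verts[e[1], ] + u * (verts[e[2], ] - verts[e[1], ])
    verts <<- rbind(verts, m)
    mi <- nrow(verts)
    sharing <- which(vapply(tris, function(tr) all(e %in% tr), logical(1)))
    for (j in rev(sharing)) {
      tr <- tris[[j]]
      o <- setdiff(tr, e)
      # keep vertex order consistent with the original winding
      rep1 <- tr; rep1[rep1 == e[2]] <- mi
      rep2 <- tr; rep2[rep2 == e[1]] <- mi
      tris[[j]] <<- rep1
      tris[[length(tris) + 1]] <<- rep2
    }
    length(sharing)
  }
  while (length(tris) < n) {
    need <- n - length(tris)
    areas <- vapply(tris, function(tr) abs(tri_area2(verts[tr, ])) / 2, 0)
    ord <- order(areas, decreasing = TRUE)
    done <- FALSE
    for (ti in ord) {
      es <- tri_edges(tris[[ti]])
      bnd <- vapply(es, function(e) on_boundary(verts[e[1], ], verts[e[2], ]),
                    logical(1))
      lens <- vapply(es, edge_len, 0)
      if (need == 1) {
        if (!any(bnd)) next
        e <- es[[which(bnd)[which.max(lens[bnd])]]]
      } else {
        e <- es[[which.max(lens)]]
      }
      split_at(ti, e)
      done <- TRUE
      break
    }
    if (!done) stop("cannot reach the requested patch count")  # unreachable
  }
  list(verts = verts, tris = tris)
}

#' Generate a piecewise-planar scene
#'
#' Partitions the frame into `n_patches` triangular regions and warps it by a
#' continuous piecewise-affine map: a shared mild base affine plus a few
#' pixels of independent jitter at every region vertex. Each region therefore
#' carries a distinct exact affine matrix while the map stays continuous
#' across shared edges, mimicking a smooth organ surface bending across
#' folds. With `n_patches = 1` the scene degenerates to a single global
#' affine warp.
#'
#' @param width,height frame size in pixels.
#' @param n_patches number of planar regions, at least 1.
#' @param seed integer seed.
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @return an `hpft_scene` whose `patch_truth` lists every (region, matrix).
#' @export
generate_piecewise_planar_scene <- function(width = 560, height = 480,
                                            n_patches = 2, seed = 1,
                                            noise_sigma = 0) {
  if (n_patches < 1) stop("n_patches must be at least 1")
  texture <- generate_textured_plane(width, height, seed)
  if (n_patches == 1) {
    B <- with_substream(seed, "piecewise_base", random_base_affine(width, height))
    return(warp_scene(texture, B, noise_sigma = noise_sigma, seed = seed))
  }
  w <- width; h <- height
  with_substream(seed, "piecewise", {
    part <- split_frame_triangles(w, h, n_patches)
    verts <- part$verts; tris <- part$tris
    B <- random_base_affine(w, h)
    base <- apply_homography(B, verts)
    jit <- matrix(stats::runif(2 * nrow(verts), -4, 4), ncol = 2)
    for (k in 0:8) {                      # shrink jitter until no fold-over
      wv <- base + jit * 0.5^k
      ok <- all(vapply(tris, function(tr) {
        sign(tri_area2(wv[tr, ])) == sign(tri_area2(verts[tr, ])) &&
          abs(tri_area2(wv[tr, ])) > 2
      }, logical(1)))
      if (ok) break
    }
    Hs <- lapply(tris, function(tr) affine_from_triangles(verts[tr, ], wv[tr, ]))

    # dense truth map: assign each reference pixel its region's affine
    tm <- array(NA_real_, c(h, w, 2))
    tgt <- matrix(0, h, w)
    gx <- matrix(rep(0:(w - 1), each = h), h, w)
    gy <- matrix(rep(0:(h - 1), w), h, w)
    for (i in seq_along(tris)) {
      tri <- verts[tris[[i]], ]
      bw <- barycentric_weights(tri, as.numeric(gx), as.numeric(gy))
      inside <- bw[, 1] >= -1e-9 & bw[, 2] >= -1e-9 & bw[, 3] >= -1e-9
      idx <- which(inside)
      if (length(idx)) {
        q <- apply_homography(Hs[[i]], cbind(gx[idx], gy[idx]))
        m1 <- tm[, , 1]; m2 <- tm[, , 2]
        m1[idx] <- q[, 1]; m2[idx] <- q[, 2]
        tm[, , 1] <- m1; tm[, , 2] <- m2
      }
      # composite the warped region into the target frame
      wtri <- wv[tris[[i]], ]
      bwT <- barycentric_weights(wtri, as.numeric(gx), as.numeric(gy))
      insT <- bwT[, 1] >= -1e-9 & bwT[, 2] >= -1e-9 & bwT[, 3] >= -1e-9
      idxT <- which(insT)
      if (length(idxT)) {
        src <- apply_homography(solve(Hs[[i]]), cbind(gx[idxT], gy[idxT]))
        tgt[idxT] <- sample_bilinear(texture, src[, 1], src[, 2], outside = 0)
      }
    }
    vis <- tm[, , 1] >= 0 & tm[, , 1] <= w - 1 & tm[, , 2] >= 0 & tm[, , 2] <= h - 1
    m1 <- tm[, , 1]; m2 <- tm[, , 2]
    m1[!vis | is.na(vis)] <- NA; m2[!vis | is.na(vis)] <- NA
    tm[, , 1] <- m1; tm[, , 2] <- m2
    if (noise_sigma > 0) {
      tgt <- tgt + matrix(stats::rnorm(h * w, 0, noise_sigma), h, w)
    }
    tgt <- round(clamp(tgt, 0, 255))
    patch_truth <- lapply(seq_along(tris), function(i) {
      list(polygon = verts[tris[[i]], , drop = FALSE], H = Hs[[i]])
    })
    new_scene(texture, tgt, tm, patch_truth, noise_sigma, seed)
  })
}

#' Paste saturated specular highlight blobs onto an image
#'
#' Adds `n_blobs` saturated (255) elliptical blobs with soft 2-px borders,
#' emulating the specular reflections of wet mucosa that cause matching
#' errors when left unmasked.
#'
#' @param image grayscale image.
#' @param n_blobs number of blobs (0 leaves the image unchanged).
#' @param seed integer seed.
#' @return list with elements `image` (modified) and `mask` (logical matrix,
#'   `TRUE` on the saturated core of every blob).
#' @export
add_specular_blobs <- function(image, n_blobs, seed = 1) {
  image <- as_gray(image)
  h <- nrow(image); w <- ncol(image)
  mask <- matrix(FALSE, h, w)
  if (n_blobs == 0) return(list(image = image, mask = mask))
  with_substream(seed, "specular", {
    for (i in seq_len(n_blobs)) {
      a <- stats::runif(1, 4, 12); b <- stats::runif(1, 4, 12)
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a + 3, w - 1 - a - 3)
      cy <- stats::runif(1, b + 3, h - 1 - b - 3)
      r <- ceiling(max(a, b)) + 3
      xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
      ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
      g <- expand.grid(x = xs, y = ys)
      u <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
      v <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
      rho <- sqrt((u / a)^2 + (v / b)^2)
      rho2 <- 1 + 2 / min(a, b)          # ~2 px soft border
      idx <- cbind(g$y + 1, g$x + 1)
      core <- rho <= 1
      soft <- rho > 1 & rho <= rho2
      image[idx[core, , drop = FALSE]] <- 255
      if (any(soft)) {
        wgt <- (rho2 - rho[soft]) / (rho2 - 1)
        old <- image[idx[soft, , drop = FALSE]]
        image[idx[soft, , drop = FALSE]] <- round(wgt * 255 + (1 - wgt) * old)
      }
      mask[idx[core, , drop = FALSE]] <- TRUE
    }
  })
  list(image = image, mask = mask)
}

#' Generate a synthetic image sequence with known inter-frame warps
#'
#' Frame `k` is the base texture warped through the cumulative composition of
#' mild per-frame affines (each within `max_rot` degrees, `max_scale`
#' fractional scale and `max_shift` px of the identity), plus per-frame
#' Gaussian noise. The cumulative matrices are the dense ground truth for
#' trajectory-level evaluation.
#'
#' @param n_frames number of frames, at least 2.
#' @param width,height frame size.
#' @param seed integer seed.
#' @param noise_sigma per-frame Gaussian noise in gray levels.
#' @param max_rot,max_scale,max_shift per-frame motion bounds.
#' @return object of class `hpft_sequence`: list of `frames` and `truth`
#'   (cumulative 3 x 3 matrices mapping frame-1 coordinates to frame k).
#' @export
generate_affine_sequence <- function(n_frames = 10, width = 560, height = 480,
                                     seed = 1, noise_sigma = 0,
                                     max_rot = 1.5, max_scale = 0.02,
                                     max_shift = 4) {
  if (n_frames < 2) stop("need at least 2 frames")
  texture <- generate_textured_plane(width, height, seed)
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  Ms <- vector("list", n_frames)
  Ms[[1]] <- diag(3)
  with_substream(seed, "sequence", {
    for (k in 2:n_frames) {
      th <- stats::runif(1, -max_rot, max_rot) * pi / 180
      sc <- stats::runif(1, 1 - max_scale, 1 + max_scale)
      tr <- stats::runif(2, -max_shift, max_shift)
      R <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
      t0 <- c(cx, cy) - R %*% c(cx, cy) + tr
      A <- rbind(cbind(R, t0), c(0, 0, 1))
      Ms[[k]] <- A %*% Ms[[k - 1]]
    }
  })
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    sc <- warp_scene(texture, Ms[[k]], noise_sigma = noise_sigma,
                     seed = sub_seed(seed, paste0("frame", k)))
    frames[[k]] <- sc$target
  }
  structure(list(frames = frames, truth = Ms, width = width, height = height,
                 noise_sigma = noise_sigma, seed = seed),
            class = "hpft_sequence")
}

#' @export
print.hpft_sequence <- function(x, ...) {
  cat(sprintf("Synthetic sequence: %d frames of %d x %d, noise sigma %.1f, seed %d\n",
              length(x$frames), x$width, x$height, x$noise_sigma, x$seed))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Writes the reference and target as PNG plus a JSON sidecar holding the
#' ground-truth patch polygons and matrices (row-major), noise level and
#' seed.
#'
#' @param scene an `hpft_scene`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "hpft_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- file.path(dir, "reference.png")
  pt <- file.path(dir, "target.png")
  png::writePNG(scene$reference / 255, pr)
  png::writePNG(scene$target / 255, pt)
  side <- list(
    noise_sigma = scene$noise_sigma,
    seed = scene$seed,
    patch_truth = lapply(scene$patch_truth, function(p) {
      list(polygon = unname(apply(p$polygon, 1, function(r) as.numeric(r),
                                  simplify = FALSE)),
           H = as.numeric(t(p$H)))
    })
  )
  pj <- file.path(dir, "scene.json")
  jsonlite::write_json(side, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(pr, pt, pj))
}

#' Read an image file as a grayscale matrix
#'
#' @param path PNG or TIFF file.
#' @return intensity matrix in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3]
  } else if (length(dim(img)) == 3) {
    img <- img[, , 1]
  }
  round(as_gray(img))
}
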