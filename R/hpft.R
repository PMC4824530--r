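# The HPFT algorithm proper. The working hypothesis is that a smooth organ
# surface is composed of many small homographic patches: Delaunay triangles
# of matched points are validated under the affine-homography hypothesis by
# normalized cross-correlation; patches that fail are split at their incircle
# centers, whose matches are searched along the epipolar segment inside the
# corresponding triangle, and the loop repeats until no new matching point
# and no new matching patch appears.

#' Control parameters for HPFT registration
#'
#' @param epsilon global acceptance threshold on the minimum descriptor
#'   distance of an epipolar-segment candidate (squared-normalized-descriptor
#'   units).
#' @param ratio nearest/second-nearest rejection threshold, applied both at
#'   initial matching and at segment search.
#' @param ncc_accept acceptance threshold on a patch's normalized
#'   cross-correlation (values close to 1 validate the planar hypothesis).
#' @param min_patch_area smallest reference-triangle area (px^2) still split
#'   after failing validation.
#' @param max_iterations hard cap on registration loops.
#' @param fb_threshold forward-backward error below which a trajectory is
#'   counted reliable (px).
#' @param budget initial feature budget for the reference image.
#' @param seed integer root seed; every random substream derives from it.
#' @param sampson_thresh RANSAC inlier threshold (px).
#' @param ransac_iter RANSAC iteration cap.
#' @param search_step candidate spacing along epipolar segments (px).
#' @param nn_radius radius (px) for nearest-match fallback when propagating
#'   points that fall outside every accepted patch.
#' @param specular_gray grayscale saturation threshold for the specular mask.
#' @param point_sigma descriptor scale (px) at non-keypoint locations.
#' @param n_scales,sigma0,contrast_thresh,edge_thresh SIFT detector settings
#'   (see [detect_features()]).
#' @return object of class `hpft_control`.
#' @export
hpft_control <- function(epsilon = 0.35, ratio = 0.8, ncc_accept = 0.9,
                         min_patch_area = 25, max_iterations = 50,
                         fb_threshold = 4, budget = 200, seed = 1,
                         sampson_thresh = 1.5, ransac_iter = 2000,
                         search_step = 1, nn_radius = 30,
                         specular_gray = 240, point_sigma = 1.6,
                         n_scales = 3, sigma0 = 1.6,
                         contrast_thresh = 0.04, edge_thresh = 10) {
  stopifnot(ratio > 0, ratio < 1,
            ncc_accept > 0, ncc_accept <= 1,
            min_patch_area > 0, max_iterations >= 1,
            epsilon > 0, fb_threshold > 0, budget >= 4,
            sampson_thresh > 0, ransac_iter >= 1, search_step > 0)
  structure(list(epsilon = epsilon, ratio = ratio, ncc_accept = ncc_accept,
                 min_patch_area = min_patch_area,
                 max_iterations = max_iterations,
                 fb_threshold = fb_threshold, budget = budget, seed = seed,
                 sampson_thresh = sampson_thresh, ransac_iter = ransac_iter,
                 search_step = search_step, nn_radius = nn_radius,
                 specular_gray = specular_gray, point_sigma = point_sigma,
                 n_scales = n_scales, sigma0 = sigma0,
                 contrast_thresh = contrast_thresh,
                 edge_thresh = edge_thresh),
            class = "hpft_control")
}

#' @export
print.hpft_control <- function(x, ...) {
  cat("HPFT control:\n")
  cat(sprintf("  epsilon %.3g, ratio %.2f, ncc_accept %.2f, min_patch_area %g px^2\n",
              x$epsilon, x$ratio, x$ncc_accept, x$min_patch_area))
  cat(sprintf("  budget %g, max_iterations %d, fb_threshold %g px, seed %d\n",
              x$budget, x$max_iterations, x$fb_threshold, x$seed))
  invisible(x)
}

# Candidate-selection rule on a vector of descriptor distances V: the argmin
# wins only if V_min / V_second_min <= ratio and V_min < epsilon; with a
# single candidate only the epsilon test applies. Ties in V_min are broken by
# smaller distance to the segment midpoint, then lower x, then lower y.
#' @keywords internal
select_candidate <- function(V, ratio, epsilon, pts = NULL) {
  if (length(V) == 0) return(0L)
  vmin <- min(V)
  cand <- which(V <= vmin + 1e-12)
  if (length(cand) > 1 && !is.null(pts)) {
    mid <- colMeans(pts[c(1, nrow(pts)), , drop = FALSE])
    dm <- sqrt((pts[cand, 1] - mid[1])^2 + (pts[cand, 2] - mid[2])^2)
    cand <- cand[order(dm, pts[cand, 1], pts[cand, 2])]
  }
  best <- cand[1]
  if (length(V) >= 2) {
    v2 <- min(V[-best])
    if (!(vmin / max(v2, 1e-300) <= ratio)) return(0L)
  }
  if (!(vmin < epsilon)) return(0L)
  best
}

# Candidate points every `step` px along a segment, endpoints included.
# Parabolic subpixel refinement of the selected candidate along the segment:
# fits a parabola to the distance profile at the argmin and its equally
# spaced neighbours. Returns the refined point.
#' @keywords internal
refine_candidate <- function(V, sel, cand, step) {
  n <- length(V)
  if (sel <= 1 || sel >= n - 1) return(cand[sel, ])
  den <- V[sel - 1] - 2 * V[sel] + V[sel + 1]
  if (!(den > 1e-12)) return(cand[sel, ])
  off <- clamp(0.5 * (V[sel - 1] - V[sel + 1]) / den, -0.5, 0.5)
  dirv <- cand[sel + 1, ] - cand[sel, ]
  cand[sel, ] + off * dirv
}

#' @keywords internal
segment_candidates <- function(segment, step) {
  len <- sqrt(sum((segment[2, ] - segment[1, ])^2))
  ts <- unique(c(seq(0, len, by = step), len))
  dirv <- if (len > 0) (segment[2, ] - segment[1, ]) / len else c(0, 0)
  cbind(segment[1, 1] + ts * dirv[1], segment[1, 2] + ts * dirv[2])
}

#' Match a reference point along an epipolar segment
#'
#' Samples candidate points every `search_step` px along the segment,
#' computes 32-element descriptors at the reference point and at every
#' candidate, and applies the two selection rules: the
#' nearest/second-nearest ratio must not exceed `ratio`, and the minimum
#' distance must fall below the global threshold `epsilon`.
#'
#' @param img_ref,img_tgt grayscale images (or precomputed descriptor
#'   contexts).
#' @param p reference point (x, y).
#' @param segment 2 x 2 matrix of segment endpoints in the target image.
#' @param control an `hpft_control`.
#' @return list with `point` (x, y), `distance`, or `NULL` when no candidate
#'   passes.
#' @export
match_point_on_segment <- function(img_ref, img_tgt, p, segment, control) {
  if (is.null(segment)) return(NULL)
  cand <- segment_candidates(segment, control$search_step)
  dp <- descriptors_at(img_ref, rbind(p), sigma = control$point_sigma)
  dc <- descriptors_at(img_tgt, cand, sigma = control$point_sigma)
  V <- as.numeric(2 - 2 * dc %*% t(dp))
  V <- pmax(V, 0)
  sel <- select_candidate(V, control$ratio, control$epsilon, cand)
  if (sel == 0L) return(NULL)
  list(point = refine_candidate(V, sel, cand, control$search_step),
       distance = V[sel])
}

# Triangulate the reference side of a match set and classify each triangle.
# Returns a list of TriPatch records; degenerate or orientation-flipped
# target triangles are flagged unmatchable.
#' @keywords internal
triangulate_matches <- function(matches) {
  pts <- cbind(matches$x_ref, matches$y_ref)
  tri <- delaunay_triangles(pts)
  out <- vector("list", nrow(tri))
  for (i in seq_len(nrow(tri))) {
    ids <- tri[i, ]
    rt <- cbind(matches$x_ref[ids], matches$y_ref[ids])
    tt <- cbind(matches$x_tgt[ids], matches$y_tgt[ids])
    a_r <- tri_area2(rt) / 2
    a_t <- tri_area2(tt) / 2
    out[[i]] <- list(vertex_ids = ids, ref_triangle = rt, tgt_triangle = tt,
                     ref_area = abs(a_r),
                     unmatchable = abs(a_t) < 1 || sign(a_t) != sign(a_r))
  }
  out
}

#' Homographic Patch Feature Transform registration
#'
#' Fits the piecewise-homographic registration between a reference and a
#' target image: lens undistortion (when a camera model is given), specular
#' masking, SIFT-32 feature detection, ratio-test matching, epipolar
#' estimation, then the iterative triangulate / validate / split-at-incenter
#' loop until no new matching point and no new matching patch is found.
#'
#' @param reference,target grayscale images of the same size (matrices on
#'   the \[0, 255\] scale, or file paths readable by [read_image()]).
#' @param camera optional `camera_model` applied to both images before
#'   detection.
#' @param control an [hpft_control()].
#' @param mask_ref,mask_tgt optional specular masks; computed with
#'   [detect_specular_mask()] when absent.
#' @return object of class `hpft`: the growing match set (`matches`), the
#'   accepted patch set (`patches`), the fundamental matrix (`F`), the
#'   per-iteration trace (`trace`), and the inputs needed by the methods.
#' @seealso [predict.hpft()], [summary.hpft()], [plot.hpft()]
#' @export
hpft <- function(reference, target, camera = NULL, control = hpft_control(),
                 mask_ref = NULL, mask_tgt = NULL) {
  cl <- match.call()
  if (is.character(reference)) reference <- read_image(reference)
  if (is.character(target)) target <- read_image(target)
  ref <- as_gray(reference); tgt <- as_gray(target)
  if (!all(dim(ref) == dim(tgt))) stop("images must share dimensions")
  if (!is.null(camera)) {
    ref <- undistort_image(ref, camera)
    tgt <- undistort_image(tgt, camera)
  }
  if (is.null(mask_ref)) {
    mask_ref <- detect_specular_mask(ref, gray_thresh = control$specular_gray)
  }
  if (is.null(mask_tgt)) {
    mask_tgt <- detect_specular_mask(tgt, gray_thresh = control$specular_gray)
  }
  feats_ref <- detect_features(ref, mask_ref, budget = control$budget,
                               seed = control$seed,
                               n_scales = control$n_scales,
                               sigma0 = control$sigma0,
                               contrast_thresh = control$contrast_thresh,
                               edge_thresh = control$edge_thresh)
  feats_tgt <- detect_features(tgt, mask_tgt, budget = Inf,
                               seed = control$seed,
                               n_scales = control$n_scales,
                               sigma0 = control$sigma0,
                               contrast_thresh = control$contrast_thresh,
                               edge_thresh = control$edge_thresh)
  m0 <- initial_match(feats_ref, feats_tgt, ratio = control$ratio)
  if (nrow(m0) == 0) stop("empty initial match set")
  Fm <- estimate_fundamental(m0, sampson_thresh = control$sampson_thresh,
                             max_iter = control$ransac_iter,
                             seed = control$seed)
  matches <- m0[Fm$inlier_indices, , drop = FALSE]
  # one match per distinct position on either side (multi-orientation
  # keypoints share coordinates; Delaunay needs distinct sites)
  matches <- matches[order(matches$distance), , drop = FALSE]
  matches <- matches[!duplicated(round(cbind(matches$x_ref, matches$y_ref), 2)) &
                       !duplicated(round(cbind(matches$x_tgt, matches$y_tgt), 2)), ,
                     drop = FALSE]
  rownames(matches) <- NULL
  n_initial <- nrow(matches)

  ctx_ref <- sift_context(ref, control$point_sigma)
  ctx_tgt <- sift_context(tgt, control$point_sigma)
  Ft <- t(Fm$F)
  patches <- list()
  accepted_keys <- character(0)
  ncc_cache <- new.env(parent = emptyenv())    # dif_h + H per triangle key
  searched <- new.env(parent = emptyenv())     # center searches already done
  trace <- data.frame(iteration = integer(0), matches = integer(0),
                      patches = integer(0), new_points = integer(0),
                      new_patches = integer(0))
  near_existing <- function(x, y, xs, ys) any(abs(xs - x) < 1 & abs(ys - y) < 1)
  it <- 0
  repeat {
    it <- it + 1
    new_points <- 0L; new_patches <- 0L
    tris <- tryCatch(triangulate_matches(matches), error = function(e) NULL)
    if (is.null(tris)) break
    pending <- list()
    for (tp in tris) {
      if (tp$unmatchable) next
      key <- paste(sort(tp$vertex_ids), collapse = "-")
      if (key %in% accepted_keys) next
      rec <- ncc_cache[[key]]
      if (is.null(rec)) {
        H <- affine_from_triangles(tp$ref_triangle, tp$tgt_triangle)
        dif <- patch_ncc(ref, tgt, tp$ref_triangle, H,
                         mask_ref = mask_ref, mask_tgt = mask_tgt)
        rec <- list(H = H, dif = dif)
        ncc_cache[[key]] <- rec
      }
      if (!is.na(rec$dif) && rec$dif >= control$ncc_accept) {
        patches[[length(patches) + 1]] <- list(
          vertex_ids = tp$vertex_ids, H = rec$H, dif_h = rec$dif,
          ref_triangle = tp$ref_triangle, tgt_triangle = tp$tgt_triangle,
          iteration = it)
        accepted_keys <- c(accepted_keys, key)
        new_patches <- new_patches + 1L
        next
      }
      if (is.na(rec$dif)) next              # unvalidatable: not split further
      if (tp$ref_area < control$min_patch_area) next
      # Step 3-4: forward search from the reference incircle center; Step 5:
      # the symmetric search from the target incircle center. Each triangle
      # is searched once; afterwards it either subdivides or stays rejected.
      fkey <- paste0(key, ":f")
      if (is.null(searched[[fkey]])) {
        searched[[fkey]] <- TRUE
        ctr <- incircle_center(tp$ref_triangle)
        if (!near_existing(ctr[1], ctr[2], matches$x_ref, matches$y_ref) &&
            !mask_ref[round(ctr[2]) + 1, round(ctr[1]) + 1]) {
          seg <- epipolar_segment_safe(Fm$F, ctr, tp$tgt_triangle)
          if (!is.null(seg)) {
            pending[[length(pending) + 1]] <-
              list(dir = "f", center = ctr,
                   cand = segment_candidates(seg, control$search_step))
          }
        }
      }
      bkey <- paste0(key, ":b")
      if (is.null(searched[[bkey]])) {
        searched[[bkey]] <- TRUE
        ctr2 <- incircle_center(tp$tgt_triangle)
        if (!near_existing(ctr2[1], ctr2[2], matches$x_tgt, matches$y_tgt) &&
            !mask_tgt[round(ctr2[2]) + 1, round(ctr2[1]) + 1]) {
          seg2 <- epipolar_segment_safe(Ft, ctr2, tp$ref_triangle)
          if (!is.null(seg2)) {
            pending[[length(pending) + 1]] <-
              list(dir = "b", center = ctr2,
                   cand = segment_candidates(seg2, control$search_step))
          }
        }
      }
    }
    if (length(pending)) {
      # one descriptor batch per image side and iteration
      dirs <- vapply(pending, `[[`, "", "dir")
      ref_pts <- do.call(rbind, c(
        lapply(pending[dirs == "f"], function(p) rbind(p$center)),
        lapply(pending[dirs == "b"], `[[`, "cand")))
      tgt_pts <- do.call(rbind, c(
        lapply(pending[dirs == "f"], `[[`, "cand"),
        lapply(pending[dirs == "b"], function(p) rbind(p$center))))
      dref <- descriptors_at(ctx_ref, ref_pts, sigma = control$point_sigma)
      dtgt <- descriptors_at(ctx_tgt, tgt_pts, sigma = control$point_sigma)
      nf <- sum(dirs == "f")
      fw_cand_sizes <- vapply(pending[dirs == "f"], function(p) nrow(p$cand), 0L)
      bw_cand_sizes <- vapply(pending[dirs == "b"], function(p) nrow(p$cand), 0L)
      fw_cand_off <- c(0L, cumsum(fw_cand_sizes))
      bw_cand_off <- c(0L, cumsum(bw_cand_sizes)) + nf
      add_x_ref <- c(); add_y_ref <- c(); add_x_tgt <- c(); add_y_tgt <- c()
      add_dist <- c(); add_src <- c()
      fi <- 0L; bi <- 0L
      for (p in pending) {
        if (p$dir == "f") {
          fi <- fi + 1L
          dc <- dtgt[(fw_cand_off[fi] + 1):(fw_cand_off[fi] + fw_cand_sizes[fi]), ,
                     drop = FALSE]
          dp <- dref[fi, ]
        } else {
          bi <- bi + 1L
          dc <- dref[(bw_cand_off[bi] + 1):(bw_cand_off[bi] + bw_cand_sizes[bi]), ,
                     drop = FALSE]
          dp <- dtgt[bi, ]
        }
        V <- pmax(as.numeric(2 - 2 * dc %*% dp), 0)
        sel <- select_candidate(V, control$ratio, control$epsilon, p$cand)
        if (sel == 0L) next
        hit <- refine_candidate(V, sel, p$cand, control$search_step)
        if (p$dir == "f") {
          if (near_existing(hit[1], hit[2], c(matches$x_tgt, add_x_tgt),
                            c(matches$y_tgt, add_y_tgt)) ||
              near_existing(p$center[1], p$center[2],
                            c(matches$x_ref, add_x_ref),
                            c(matches$y_ref, add_y_ref))) next
          add_x_ref <- c(add_x_ref, p$center[1])
          add_y_ref <- c(add_y_ref, p$center[2])
          add_x_tgt <- c(add_x_tgt, hit[1]); add_y_tgt <- c(add_y_tgt, hit[2])
          add_src <- c(add_src, "center-forward")
        } else {
          if (near_existing(hit[1], hit[2], c(matches$x_ref, add_x_ref),
                            c(matches$y_ref, add_y_ref)) ||
              near_existing(p$center[1], p$center[2],
                            c(matches$x_tgt, add_x_tgt),
                            c(matches$y_tgt, add_y_tgt))) next
          add_x_ref <- c(add_x_ref, hit[1]); add_y_ref <- c(add_y_ref, hit[2])
          add_x_tgt <- c(add_x_tgt, p$center[1])
          add_y_tgt <- c(add_y_tgt, p$center[2])
          add_src <- c(add_src, "center-backward")
        }
        add_dist <- c(add_dist, V[sel])
      }
      if (length(add_x_ref)) {
        new_points <- length(add_x_ref)
        matches <- rbind(matches, data.frame(
          ref_id = NA_integer_, tgt_id = NA_integer_,
          x_ref = add_x_ref, y_ref = add_y_ref,
          x_tgt = add_x_tgt, y_tgt = add_y_tgt,
          distance = add_dist, source = add_src, stringsAsFactors = FALSE))
        rownames(matches) <- NULL
      }
    }
    trace <- rbind(trace, data.frame(
      iteration = it, matches = nrow(matches), patches = length(patches),
      new_points = new_points, new_patches = new_patches))
    # no new points means the next triangulation is unchanged, so no new
    # patches can appear either: the fixpoint is reached
    if (new_points == 0L || it >= control$max_iterations) break
  }
  structure(list(matches = matches, patches = patches, F = Fm$F,
                 inlier_count = n_initial, iterations = it, trace = trace,
                 control = control, reference = ref, target = tgt,
                 mask_ref = mask_ref, mask_tgt = mask_tgt,
                 image_dim = dim(ref), call = cl),
            class = "hpft")
}

#' @export
print.hpft <- function(x, ...) {
  cat("Homographic Patch Feature Transform registration\n")
  cat(sprintf("  %d x %d images; %d matched points (%d initial inliers), %d matched patches\n",
              x$image_dim[2], x$image_dim[1], nrow(x$matches),
              x$inlier_count, length(x$patches)))
  cat(sprintf("  converged after %d iteration(s)\n", x$iterations))
  invisible(x)
}

#' Summarize an HPFT registration
#'
#' @param object an `hpft` fit.
#' @param ... unused.
#' @return an `hpft_summary` with match-source counts, patch similarity
#'   statistics and the iteration trace.
#' @export
summary.hpft <- function(object, ...) {
  difs <- vapply(object$patches, `[[`, 0, "dif_h")
  areas <- vapply(object$patches, function(p) abs(tri_area2(p$ref_triangle)) / 2, 0)
  s <- list(
    n_matches = nrow(object$matches),
    by_source = table(object$matches$source),
    n_patches = length(object$patches),
    dif_h = if (length(difs)) summary(difs) else NULL,
    patch_area = if (length(areas)) summary(areas) else NULL,
    iterations = object$iterations,
    trace = object$trace,
    coverage = if (length(areas)) sum(areas) / prod(object$image_dim) else 0
  )
  class(s) <- "hpft_summary"
  s
}

#' @export
print.hpft_summary <- function(x, ...) {
  cat(sprintf("Matched points: %d (", x$n_matches))
  cat(paste(names(x$by_source), as.integer(x$by_source), sep = ": ",
            collapse = ", "))
  cat(")\n")
  cat(sprintf("Matched patches: %d, covering %.1f%% of the frame\n",
              x$n_patches, 100 * x$coverage))
  if (!is.null(x$dif_h)) {
    cat(sprintf("Patch NCC: min %.3f, median %.3f, max %.3f\n",
                x$dif_h[["Min."]], x$dif_h[["Median"]], x$dif_h[["Max."]]))
  }
  cat(sprintf("Iterations: %d\n", x$iterations))
  invisible(x)
}

#' Patch homographies of an HPFT fit
#'
#' @param object an `hpft` fit.
#' @param ... unused.
#' @return list of 3 x 3 affine matrices, one per accepted patch.
#' @export
coef.hpft <- function(object, ...) {
  lapply(object$patches, `[[`, "H")
}

#' Epipolar residuals of the matched points
#'
#' @param object an `hpft` fit.
#' @param ... unused.
#' @return Sampson distances (px) of every match against the fitted
#'   fundamental matrix.
#' @export
residuals.hpft <- function(object, ...) {
  sampson_distance(object$F,
                   cbind(object$matches$x_ref, object$matches$y_ref),
                   cbind(object$matches$x_tgt, object$matches$y_tgt))
}

#' Map reference points through an HPFT registration
#'
#' Each point inside an accepted patch is mapped by that patch's affine
#' homography (the largest containing patch, whose long vertex baseline
#' amplifies localization noise least); points
#' outside every patch move by the translation of the nearest matched point
#' within `control$nn_radius` px; remaining points are lost (`NA`).
#'
#' @param object an `hpft` fit.
#' @param newdata n x 2 matrix of reference (x, y) points; defaults to the
#'   matched reference points.
#' @param ... unused.
#' @return n x 2 matrix of target positions with attribute `method`
#'   (`"patch"`, `"nearest"` or `"lost"` per point).
#' @export
predict.hpft <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- cbind(object$matches$x_ref, object$matches$y_ref)
  }
  pts <- matrix(as.numeric(newdata), ncol = 2)
  n <- nrow(pts)
  out <- matrix(NA_real_, n, 2)
  method <- rep("lost", n)
  if (length(object$patches)) {
    # among containing patches prefer the longest-baseline (largest) one:
    # its affine amplifies vertex localization noise least
    areas <- vapply(object$patches,
                    function(p) abs(tri_area2(p$ref_triangle)) / 2, 0)
    best_area <- rep(-Inf, n)
    for (k in seq_along(object$patches)) {
      p <- object$patches[[k]]
      bw <- barycentric_weights(p$ref_triangle, pts[, 1], pts[, 2])
      inside <- bw[, 1] >= -1e-9 & bw[, 2] >= -1e-9 & bw[, 3] >= -1e-9
      take <- which(inside & areas[k] > best_area)
      if (length(take)) {
        out[take, ] <- apply_homography(p$H, pts[take, , drop = FALSE])
        method[take] <- "patch"
        best_area[take] <- areas[k]
      }
    }
  }
  left <- which(method == "lost")
  if (length(left) && nrow(object$matches)) {
    mx <- object$matches$x_ref; my <- object$matches$y_ref
    for (i in left) {
      d2 <- (mx - pts[i, 1])^2 + (my - pts[i, 2])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= object$control$nn_radius) {
        out[i, ] <- pts[i, ] + c(object$matches$x_tgt[j] - mx[j],
                                 object$matches$y_tgt[j] - my[j])
        method[i] <- "nearest"
      }
    }
  }
  attr(out, "method") <- method
  out
}

#' Plot an HPFT registration
#'
#' @param x an `hpft` fit.
#' @param which `"matches"` (reference image with matched points and motion
#'   vectors), `"patches"` (accepted triangles), or `"trace"` (growth of the
#'   match and patch sets per iteration).
#' @param ... unused.
#' @export
plot.hpft <- function(x, which = c("matches", "patches", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(x$trace$iteration, x$trace$matches, type = "b", pch = 16,
                   xlab = "iteration", ylab = "count",
                   main = "HPFT iteration trace",
                   ylim = c(0, max(x$trace$matches)))
    graphics::lines(x$trace$iteration, x$trace$patches, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("bottomright", c("matched points", "matched patches"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
    return(invisible(x))
  }
  h <- x$image_dim[1]; w <- x$image_dim[2]
  graphics::plot(NA, xlim = c(0, w - 1), ylim = c(h - 1, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)",
                 main = sprintf("HPFT %s", which))
  graphics::rasterImage(x$reference / 255, 0, h - 1, w - 1, 0)
  if (which == "matches") {
    graphics::points(x$matches$x_ref, x$matches$y_ref, col = "dodgerblue",
                     pch = 16, cex = 0.5)
    graphics::segments(x$matches$x_ref, x$matches$y_ref,
                       x$matches$x_tgt, x$matches$y_tgt,
                       col = grDevices::adjustcolor("orange", 0.6))
  } else {
    for (p in x$patches) {
      graphics::polygon(p$ref_triangle[, 1], p$ref_triangle[, 2],
                        border = "green3")
    }
  }
  invisible(x)
}

#' Write the accepted patches of a fit as JSON
#'
#' One record per patch: vertex ids, the 3 x 3 homography (row-major) and
#' the NCC score.
#'
#' @param fit an `hpft` fit.
#' @param path output file.
#' @export
write_patches <- function(fit, path) {
  rec <- lapply(fit$patches, function(p) {
    list(vertex_ids = as.integer(p$vertex_ids),
         H = as.numeric(t(p$H)), dif_h = p$dif_h,
         iteration = p$iteration)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
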