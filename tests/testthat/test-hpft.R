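# The iterative registration core and its S3 interface.

test_that("identical images register to themselves in one loop", {
  tex <- fx_texture(240, 180, 7)
  fit <- hpft(tex, tex, control = hpft_control(seed = 1))
  expect_s3_class(fit, "hpft")
  expect_equal(fit$iterations, 1)
  expect_true(all(fit$matches$distance < 1e-9))
  expect_gt(length(fit$patches), 0)
  difs <- vapply(fit$patches, `[[`, 0, "dif_h")
  expect_true(all(abs(difs - 1) < 1e-9))
  # every patch homography is the identity here
  for (p in fit$patches[1:5]) {
    expect_lt(max(abs(p$H - diag(3))), 1e-9)
  }
})

test_that("mismatched dimensions and empty inputs raise errors", {
  tex <- fx_texture(240, 180, 7)
  expect_error(hpft(tex, tex[1:100, ]), "share dimensions")
  flat <- matrix(100, 180, 240)
  expect_error(hpft(flat, flat), "untextured")
})

test_that("noise-free exact correspondences recover the truth matrix", {
  # with exact vertex correspondences the estimated patch homography equals
  # the ground-truth affine to numerical precision
  H <- fx_affine_H()
  set.seed(13)
  pts <- cbind(runif(40, 10, 200), runif(40, 10, 150))
  tgt <- cbind(pts, 1) %*% t(H)
  m <- data.frame(x_ref = pts[, 1], y_ref = pts[, 2],
                  x_tgt = tgt[, 1], y_tgt = tgt[, 2])
  tris <- hpft:::triangulate_matches(m)
  for (tp in tris) {
    Hh <- affine_from_triangles(tp$ref_triangle, tp$tgt_triangle)
    expect_lt(max(abs(Hh - H)), 1e-6)
  }
})

test_that("orientation-flipped triangles are excluded as unmatchable", {
  m <- data.frame(x_ref = c(0, 10, 0, 10), y_ref = c(0, 0, 10, 10),
                  x_tgt = c(10, 0, 10, 0), y_tgt = c(0, 0, 10, 10))
  tris <- hpft:::triangulate_matches(m)
  expect_true(all(vapply(tris, `[[`, TRUE, "unmatchable")))
})

test_that("the registration trace is monotone and terminates", {
  fit <- fx_small_fit()
  tr <- fit$trace
  expect_true(all(diff(tr$matches) >= 0))
  expect_true(all(diff(tr$patches) >= 0))
  expect_lte(fit$iterations, fit$control$max_iterations)
  # final iteration added nothing or the cap was hit
  last <- tr[nrow(tr), ]
  expect_true(last$new_points == 0 ||
                fit$iterations == fit$control$max_iterations)
})

test_that("registration is deterministic under a fixed seed", {
  sc <- fx_small_pair()
  fit1 <- hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  fit2 <- hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  expect_identical(fit1$matches, fit2$matches)
  expect_identical(fit1$trace, fit2$trace)
})

test_that("segment candidate selection applies both gating rules", {
  sel <- hpft:::select_candidate
  expect_equal(sel(c(0.05, 0.90, 0.85), 0.8, 0.5), 1L)   # ratio 0.056, eps ok
  expect_equal(sel(c(0.45, 0.50), 0.8, 0.5), 0L)          # ratio 0.9 > 0.8
  expect_equal(sel(c(0.70, 4.0), 0.8, 0.5), 0L)           # V_min >= epsilon
  expect_equal(sel(c(0.2), 0.8, 0.5), 1L)                 # single: eps only
  expect_equal(sel(c(0.6), 0.8, 0.5), 0L)
})

test_that("match_point_on_segment finds the true correspondence", {
  sc <- fx_small_pair()
  H <- fx_affine_H()
  ctl <- hpft_control(seed = 1)
  p <- c(120, 90)
  truth <- as.numeric(H %*% c(p, 1))[1:2]
  seg <- rbind(truth - c(12, 0), truth + c(12, 0))
  hit <- match_point_on_segment(sc$reference, sc$target, p, seg, ctl)
  expect_false(is.null(hit))
  expect_lt(sqrt(sum((hit$point - truth)^2)), 1.5)
  expect_null(match_point_on_segment(sc$reference, sc$target, p, NULL, ctl))
})

test_that("predict maps through patches and falls back to neighbors", {
  fit <- fx_small_fit()
  H <- fx_affine_H()
  set.seed(14)
  pts <- cbind(runif(50, 30, 210), runif(50, 30, 150))
  mapped <- predict(fit, pts)
  method <- attr(mapped, "method")
  truth <- cbind(pts, 1) %*% t(H)
  ok <- method != "lost"
  err <- sqrt((mapped[ok, 1] - truth[ok, 1])^2 +
                (mapped[ok, 2] - truth[ok, 2])^2)
  expect_gt(mean(ok), 0.9)
  expect_lt(stats::median(err), 2)
  expect_true(any(method == "patch"))
})

test_that("model methods summarize the fit coherently", {
  fit <- fx_small_fit()
  expect_output(print(fit), "Homographic Patch Feature Transform")
  s <- summary(fit)
  expect_s3_class(s, "hpft_summary")
  expect_output(print(s), "Matched patches")
  expect_equal(s$n_matches, nrow(fit$matches))
  cf <- coef(fit)
  expect_length(cf, length(fit$patches))
  expect_true(all(vapply(cf, function(H) all(H[3, ] == c(0, 0, 1)), TRUE)))
  r <- residuals(fit)
  expect_length(r, nrow(fit$matches))
  expect_true(all(r >= 0))
  # plotting works headlessly
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  plot(fit, which = "matches")
  plot(fit, which = "patches")
  plot(fit, which = "trace")
  grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("the transposed fundamental matrix drives the reverse search", {
  # Step 5 symmetry: the epipolar constraint for target-side centers is F^T,
  # so inlier pairs satisfy the reverse line equation too
  fit <- fx_small_fit()
  m <- fit$matches[fit$matches$source == "initial", ][1:10, ]
  for (i in seq_len(nrow(m))) {
    l <- epipolar_line(t(fit$F), c(m$x_tgt[i], m$y_tgt[i]))
    expect_lt(abs(l[1] * m$x_ref[i] + l[2] * m$y_ref[i] + l[3]), 2.5)
  }
})

test_that("specular highlights never seed matched points", {
  tex <- fx_texture(240, 180, 15)
  b <- add_specular_blobs(tex, 8, seed = 3)
  sc <- warp_scene(b$image, fx_affine_H(), noise_sigma = 2, seed = 5)
  fit <- hpft(sc$reference, sc$target, control = hpft_control(seed = 1))
  mask <- detect_specular_mask(sc$reference)
  idx <- cbind(clamp(round(fit$matches$y_ref), 0, 179) + 1,
               clamp(round(fit$matches$x_ref), 0, 239) + 1)
  expect_equal(sum(mask[idx]), 0)
})
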